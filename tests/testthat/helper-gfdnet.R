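# shared fixtures and oracles, all built in code

# central-difference gradient of f at p (step small enough to keep
# probability rows within the row-sum validator's tolerance)
num_grad <- function(f, p, h = 5e-7) {
  g <- p * 0
  for (i in seq_along(p)) {
    a <- p; b <- p
    a[i] <- a[i] + h
    b[i] <- b[i] - h
    g[i] <- (f(a) - f(b)) / (2 * h)
  }
  g
}

# random probability batch (rows sum to 1) and matching one-hot targets
random_batch <- function(n, C, seed) {
  set.seed(seed)
  z <- matrix(rnorm(n * C), n, C)
  probs <- exp(z) / rowSums(exp(z))
  targets <- diag(C)[sample.int(C, n, replace = TRUE), , drop = FALSE]
  list(probs = probs, targets = targets)
}

# smooth unclipped phantom for noise-recovery oracles: intensities stay in
# (0.3, 0.7) so added Gaussian noise at sigma <= 0.1 almost never clips
smooth_phantom <- function(H = 176, W = 208) {
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  0.5 + 0.2 * sin(y / 30) * cos(x / 40)
}

# 256-bin Shannon entropy of an 8-bit image
hist_entropy <- function(px255) {
  h <- tabulate(round(px255) + 1L, 256L)
  p <- h[h > 0] / sum(h)
  -sum(p * log2(p))
}

# desk-scale model/training setup used by the training sanity checks:
# 8x-downsampled 22 x 26 slices through a 3-stage (8/16/32) network
desk_model_config <- function(n_classes = 4L) {
  model_config(stage_widths = c(8L, 16L, 32L), gn_groups = 4L,
               head_width = 32L, n_classes = n_classes,
               input_shape = c(22L, 26L))
}

desk_dataset <- function(n, seed, sigma = 0.05, proportions = NULL) {
  spec <- if (is.null(proportions))
    synthetic_spec(n_total = n, noise_sigma = sigma, seed = seed)
  else
    synthetic_spec(n_total = n, class_proportions = proportions,
                   noise_sigma = sigma, seed = seed)
  downsample(generate_dataset(spec), 8L)
}
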