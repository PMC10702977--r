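#' Specification of the synthetic brain-slice generator
#'
#' Describes a population of 176 x 208 grayscale phantom slices: a bright
#' elliptical "brain" on a black background with smooth interior texture and
#' a central dark "ventricle" whose area grows with dementia severity (the
#' atrophy signal), plus additive Gaussian noise. Class proportions default
#' to the severely imbalanced train-set ratios of the four-stage dementia
#' collection (2050 : 1075 : 573 : 42).
#'
#' @param n_total Total number of slices, >= 4.
#' @param class_proportions Length-4 simplex vector (summing to 1) of class
#'   shares in canonical class order.
#' @param atrophy_levels Four strictly increasing scalars in \[0, 1\]
#'   controlling ventricle enlargement per class (none < very mild < mild <
#'   moderate).
#' @param noise_sigma Additive Gaussian noise standard deviation on the unit
#'   intensity scale.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the spec.
#' @param shape Integer `(H, W)` of the generated slices.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_total = 400L,
                           class_proportions = c(2050, 1075, 573, 42) / 3740,
                           atrophy_levels = c(0.1, 0.4, 0.7, 1.0),
                           noise_sigma = 0.05, seed = 1L,
                           shape = c(176L, 208L)) {
  stopifnot(n_total >= 4, length(class_proportions) == 4,
            abs(sum(class_proportions) - 1) < 1e-8,
            length(atrophy_levels) == 4,
            all(diff(atrophy_levels) > 0),
            all(atrophy_levels >= 0), all(atrophy_levels <= 1),
            noise_sigma >= 0)
  structure(list(n_total = as.integer(n_total),
                 class_proportions = class_proportions,
                 atrophy_levels = atrophy_levels,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 shape = as.integer(shape)),
            class = "synthetic_spec")
}

#' Largest-remainder apportionment of n samples to class proportions
#'
#' Each class gets `floor(n * p)` samples; the leftovers go to the classes
#' with the largest fractional remainders (earlier classes win ties).
#'
#' @param n Total count.
#' @param proportions Simplex vector.
#' @return Integer vector summing to `n`.
#' @examples
#' largest_remainder_counts(400, c(2050, 1075, 573, 42) / 3740)  # 219 115 61 5
#' @export
largest_remainder_counts <- function(n, proportions) {
  quota <- n * proportions
  counts <- floor(quota)
  rem <- quota - counts
  short <- n - sum(counts)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  as.integer(counts)
}

#' Generate one phantom slice
#'
#' Draws a slice of the given class from the current RNG state: jittered
#' brain ellipse, low-amplitude smooth texture, a central ventricle whose
#' axes scale with `atrophy_levels[class_idx]` (slight whole-brain shrinkage
#' accompanies higher atrophy), then additive Gaussian noise clipped to
#' \[0, 1\]. The brain never touches the image border, so corner intensities
#' stay at the noise level.
#'
#' @param class_idx Class label in `1..4`.
#' @param spec A [synthetic_spec()].
#' @return An `image_slice` (unit scale, stage `"raw"`).
#' @export
generate_slice <- function(class_idx, spec = synthetic_spec()) {
  stopifnot(class_idx >= 1, class_idx <= 4)
  H <- spec$shape[1]; W <- spec$shape[2]
  a <- spec$atrophy_levels[class_idx]
  cy <- H / 2 + runif(1, -2, 2)
  cx <- W / 2 + runif(1, -2, 2)
  shrink <- 1 - 0.04 * a                      # mild global atrophy
  ry <- 0.465 * H * shrink * runif(1, 0.98, 1.02)
  rx <- 0.45 * W * shrink * runif(1, 0.98, 1.02)
  vs <- (1 + 1.8 * a) * runif(1, 0.95, 1.05)  # ventricle enlargement
  rvy <- 12 * vs
  rvx <- 8 * vs
  y <- matrix(seq_len(H), H, W)
  x <- matrix(seq_len(W), H, W, byrow = TRUE)
  d_brain <- sqrt(((y - cy) / ry)^2 + ((x - cx) / rx)^2)
  brain <- stats::plogis((1 - d_brain) / 0.02)
  d_vent <- sqrt(((y - cy) / rvy)^2 + ((x - cx) / rvx)^2)
  vent <- stats::plogis((1 - d_vent) / 0.06)
  tex <- matrix(0, H, W)
  for (i in 1:4) {
    fy <- runif(1, 0.5, 3) / H; fx <- runif(1, 0.5, 3) / W
    tex <- tex + 0.03 * cos(2 * pi * (fy * y + fx * x) + runif(1, 0, 2 * pi))
  }
  tissue <- 0.55 + tex
  img <- brain * tissue * (1 - 0.85 * vent)
  if (spec$noise_sigma > 0)
    img <- img + rnorm(H * W, sd = spec$noise_sigma)
  image_slice(pmin(pmax(img, 0), 1), scale = "unit", stage = "raw")
}

#' Generate a labeled synthetic dataset
#'
#' Per-class counts come from [largest_remainder_counts()] applied to
#' `spec$class_proportions`; slices are generated per class and shuffled,
#' all deterministically from `spec$seed`. A class receiving zero samples
#' raises a warning.
#'
#' @param spec A [synthetic_spec()].
#' @return A `labeled_dataset` with the canonical [gfd_classes()] names.
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_total = 8, seed = 7))
#' class_counts(ds)
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  counts <- largest_remainder_counts(spec$n_total, spec$class_proportions)
  if (any(counts == 0))
    warning(sprintf("class(es) %s received 0 samples",
                    paste(which(counts == 0), collapse = ", ")),
            call. = FALSE)
  with_seed(spec$seed, {
    slices <- vector("list", sum(counts))
    labels <- integer(sum(counts))
    i <- 0L
    for (ci in 1:4) {
      for (k in seq_len(counts[ci])) {
        i <- i + 1L
        slices[[i]] <- generate_slice(ci, spec)
        labels[i] <- ci
      }
    }
    ord <- sample.int(length(labels))
    labeled_dataset(slices[ord], labels[ord], gfd_classes())
  })
}

#' Downsample a slice or dataset by an integer factor
#'
#' Bilinear resize to `floor(H / factor) x floor(W / factor)`; used to bring
#' full-resolution slices down to desk-scale training sizes.
#'
#' @param x An `image_slice` or `labeled_dataset`.
#' @param factor Integer >= 1.
#' @return Object of the same type at the reduced resolution.
#' @export
downsample <- function(x, factor = 4L) {
  if (inherits(x, "labeled_dataset")) {
    x$slices <- lapply(x$slices, downsample, factor = factor)
    return(x)
  }
  stopifnot(inherits(x, "image_slice"))
  if (factor == 1L) return(x)
  u <- as_unit_scale(x)
  h <- nrow(u$pixels) %/% factor; w <- ncol(u$pixels) %/% factor
  r <- EBImage::resize(t(u$pixels), w = w, h = h)
  out <- u
  out$pixels <- pmin(pmax(t(as.matrix(r)), 0), 1)
  out
}
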