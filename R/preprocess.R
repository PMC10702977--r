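#' Configuration of the image-restoration chain
#'
#' Parameters of the denoise/enhance/augment chain applied to raw slices:
#' Non-Local Means (NLM) with a noise level estimated from the image itself,
#' then Contrast-Limited Adaptive Histogram Equalization (CLAHE), then
#' seeded affine augmentation.
#'
#' @param patch_size NLM patch radius (pixels); patches are
#'   `(2*patch_size+1)` square. Default 2.
#' @param patch_distance NLM search radius (pixels); candidate pixels come
#'   from a `(2*patch_distance+1)` square window. Default 1.
#' @param clahe_clip CLAHE clip limit (unitless contrast-amplification
#'   bound). Default 2.6.
#' @param clahe_tiles Integer length-2 vector, the tile grid (rows, cols).
#'   Default `c(8, 8)`.
#' @param sigma_multiplier Factor applied to the estimated noise sigma to set
#'   the NLM filtering strength `h`. Default 1.
#' @param shift_frac,rotate_deg,rescale_range,flip_prob Augmentation ranges:
#'   maximum shift as a fraction of each dimension, maximum rotation in
#'   degrees, multiplicative rescale interval, and the probability of each
#'   of horizontal and vertical flip.
#'
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(patch_size = 2, patch_distance = 1,
                              clahe_clip = 2.6, clahe_tiles = c(8, 8),
                              sigma_multiplier = 1,
                              shift_frac = 0.1, rotate_deg = 15,
                              rescale_range = c(0.9, 1.1), flip_prob = 0.5) {
  stopifnot(patch_size >= 1, patch_distance >= 1, sigma_multiplier > 0,
            length(clahe_tiles) == 2, all(clahe_tiles >= 1),
            length(rescale_range) == 2, rescale_range[1] <= rescale_range[2],
            flip_prob >= 0, flip_prob <= 1)
  if (clahe_clip <= 0) stop("`clahe_clip` must be > 0", call. = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 patch_distance = as.integer(patch_distance),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 sigma_multiplier = sigma_multiplier,
                 shift_frac = shift_frac, rotate_deg = rotate_deg,
                 rescale_range = rescale_range, flip_prob = flip_prob),
            class = "preprocess_config")
}

#' Estimate the additive Gaussian noise level of a slice
#'
#' Robust noise estimate from the finest-scale wavelet detail: the image is
#' decomposed with one level of an orthonormal 2D Haar transform and sigma
#' is the median absolute deviation of the diagonal detail coefficients
#' divided by 0.6745 (the MAD of a standard normal). Smooth image structure
#' contributes little to the diagonal detail, so the estimate tracks the
#' noise rather than the anatomy.
#'
#' @param img An `image_slice` on the unit scale.
#' @return Non-negative scalar sigma in unit-intensity units; 0 for a
#'   constant image.
#' @export
estimate_noise_sigma <- function(img) {
  stopifnot(inherits(img, "image_slice"))
  if (img$scale != "unit")
    stop("noise estimation expects a unit-scale slice", call. = FALSE)
  x <- img$pixels
  h <- 2L * (nrow(x) %/% 2L); w <- 2L * (ncol(x) %/% 2L)
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  a <- x[seq(1, h, 2), seq(1, w, 2)]; b <- x[seq(2, h, 2), seq(1, w, 2)]
  c_ <- x[seq(1, h, 2), seq(2, w, 2)]; d <- x[seq(2, h, 2), seq(2, w, 2)]
  hh <- (a - b - c_ + d) / 2          # orthonormal Haar diagonal detail
  median(abs(hh)) / 0.6745
}

#' Non-Local Means denoising
#'
#' Replaces each pixel by a similarity-weighted average over a small search
#' window, with patch similarity measured as mean squared difference over
#' `(2*patch_size+1)` square patches and weights `exp(-d2 / h^2)` at
#' filtering strength `h = sigma_multiplier * sigma`. `sigma = 0` disables
#' filtering and returns the input unchanged.
#'
#' @param img An `image_slice` on the unit scale.
#' @param sigma Noise standard deviation (unit-intensity units), typically
#'   from [estimate_noise_sigma()]; must be >= 0.
#' @param cfg A [preprocess_config()].
#' @return An `image_slice` with `stage = "denoised"`.
#' @export
nlm_denoise <- function(img, sigma, cfg = preprocess_config()) {
  stopifnot(inherits(img, "image_slice"))
  if (img$scale != "unit")
    stop("NLM expects a unit-scale slice", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single non-negative number", call. = FALSE)
  if (sigma == 0) { img$stage <- "denoised"; return(img) }
  h <- cfg$sigma_multiplier * sigma
  out <- nlm_filter(img$pixels, h, cfg$patch_size, cfg$patch_distance)
  set_pixels(img, out, stage = "denoised")
}

#' CLAHE contrast enhancement
#'
#' Contrast-Limited Adaptive Histogram Equalization over a tile grid with
#' the configured clip limit, on the 8-bit intensity scale. The underlying
#' equalization requires image dimensions divisible by the tile counts, so
#' the slice is padded by edge replication to the next multiple and cropped
#' back afterwards.
#'
#' @param img An `image_slice` (any scale; converted to 8-bit internally).
#' @param cfg A [preprocess_config()]; `clahe_clip` must be > 0.
#' @return An `image_slice` on the `"uint8"` scale with `stage = "enhanced"`.
#' @export
clahe_enhance <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(img, "image_slice"))
  if (cfg$clahe_clip <= 0) stop("`clahe_clip` must be > 0", call. = FALSE)
  u <- as_unit_scale(img)
  x <- u$pixels
  nx <- cfg$clahe_tiles[2]; ny <- cfg$clahe_tiles[1]
  # EBImage images are (x = columns of the scene, y); our matrices are H x W
  # with rows = y, so pass the transpose and tile counts accordingly.
  t_ <- t(x)
  padx <- (nx - nrow(t_) %% nx) %% nx
  pady <- (ny - ncol(t_) %% ny) %% ny
  if (padx > 0) t_ <- rbind(t_, t_[rep(nrow(t_), padx), , drop = FALSE])
  if (pady > 0) t_ <- cbind(t_, t_[, rep(ncol(t_), pady), drop = FALSE])
  eq <- EBImage::clahe(t_, nx = nx, ny = ny, limit = cfg$clahe_clip)
  eq <- t(eq[seq_len(ncol(x)), seq_len(nrow(x)), drop = FALSE])
  out <- image_slice(pmin(pmax(round(eq * 255), 0), 255), scale = "uint8",
                     stage = "raw")
  out$stage <- "enhanced"
  out
}

#' Full restoration of a single slice
#'
#' The fixed chain: estimate the noise sigma, NLM-denoise at that sigma,
#' then CLAHE. Equal by construction to composing the three operations by
#' hand.
#'
#' @inheritParams clahe_enhance
#' @return An `image_slice` with `stage = "enhanced"` on the 8-bit scale.
#' @export
preprocess_slice <- function(img, cfg = preprocess_config()) {
  u <- as_unit_scale(img)
  clahe_enhance(nlm_denoise(u, estimate_noise_sigma(u), cfg), cfg)
}

# random affine warp of one slice: shift + rotation + rescale + flips,
# bilinear interpolation, background filled with 0 (skull-stripped black)
augment_slice <- function(img, cfg) {
  u <- as_unit_scale(img)
  h <- nrow(u$pixels); w <- ncol(u$pixels)
  ang <- runif(1, -cfg$rotate_deg, cfg$rotate_deg) * pi / 180
  sc <- runif(1, cfg$rescale_range[1], cfg$rescale_range[2])
  tx <- runif(1, -cfg$shift_frac, cfg$shift_frac) * w
  ty <- runif(1, -cfg$shift_frac, cfg$shift_frac) * h
  fh <- runif(1) < cfg$flip_prob
  fv <- runif(1) < cfg$flip_prob
  sx <- if (fh) -sc else sc
  sy <- if (fv) -sc else sc
  # rotation+scale about the image centre, then translation; EBImage::affine
  # maps scene coords (x right, y down) via cbind(x, y, 1) %*% m
  cx <- w / 2; cy <- h / 2
  A <- matrix(c(sx * cos(ang), sx * sin(ang),
                -sy * sin(ang), sy * cos(ang)), 2, 2)
  off <- c(cx + tx, cy + ty) - A %*% c(cx, cy)
  m <- rbind(t(A), as.numeric(off))        # 3 x 2 as EBImage expects
  warped <- EBImage::affine(t(u$pixels), m, filter = "bilinear",
                            output.dim = c(w, h), bg.col = 0)
  out <- set_pixels(u, t(as.matrix(warped)), stage = "augmented")
  out
}

#' Augment a labeled dataset by seeded random affine warps
#'
#' Returns the original slices plus `(factor - 1) * N` augmented copies,
#' each produced by a random shift, rotation, rescale and horizontal /
#' vertical flips drawn from the ranges in `cfg`. Labels are preserved;
#' augmented slices carry `stage = "augmented"`. The default `factor = 2`
#' doubles the dataset.
#'
#' @param ds A `labeled_dataset`.
#' @param factor Integer >= 1; 1 returns the dataset unchanged.
#' @param seed Integer seed; the same seed reproduces the same augmented set.
#' @param cfg A [preprocess_config()] providing the augmentation ranges.
#' @return A `labeled_dataset` of size `factor * N`.
#' @export
augment_dataset <- function(ds, factor = 2L, seed = 1L,
                            cfg = preprocess_config()) {
  stopifnot(inherits(ds, "labeled_dataset"))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  n <- length(ds$slices)
  if (factor == 1L || n == 0L) return(ds)
  slices <- ds$slices; labels <- ds$labels
  with_seed(seed, {
    for (rep_i in seq_len(factor - 1L)) {
      for (i in seq_len(n)) {
        slices[[length(slices) + 1L]] <- augment_slice(ds$slices[[i]], cfg)
        labels <- c(labels, ds$labels[i])
      }
    }
  })
  labeled_dataset(slices, labels, ds$class_names)
}

# evaluate `code` under a temporary RNG seed, restoring the caller's RNG
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
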