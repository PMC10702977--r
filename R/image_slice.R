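#' A single 2D grayscale brain slice
#'
#' Lightweight container for one slice: a numeric intensity matrix plus the
#' declared intensity scale and a provenance tag recording which processing
#' stage produced it.
#'
#' @param pixels Numeric matrix, H x W, H and W both >= 16.
#' @param scale `"unit"` (float intensities in \[0, 1\]) or `"uint8"`
#'   (integers in \[0, 255\]).
#' @param stage Provenance tag: one of `"raw"`, `"denoised"`, `"enhanced"`,
#'   `"augmented"`.
#'
#' @return An object of class `image_slice`.
#' @examples
#' s <- image_slice(matrix(0.5, 32, 32))
#' dim(s)
#' @export
image_slice <- function(pixels, scale = c("unit", "uint8"),
                        stage = c("raw", "denoised", "enhanced", "augmented")) {
  scale <- match.arg(scale)
  stage <- match.arg(stage)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("slice must be at least 16 x 16", call. = FALSE)
  rng <- range(pixels)
  lim <- if (scale == "unit") c(0, 1) else c(0, 255)
  if (rng[1] < lim[1] - 1e-9 || rng[2] > lim[2] + 1e-9)
    stop(sprintf("pixels outside declared '%s' range [%g, %g]",
                 scale, lim[1], lim[2]), call. = FALSE)
  structure(list(pixels = pixels, scale = scale, stage = stage),
            class = "image_slice")
}

#' @export
dim.image_slice <- function(x) dim(x$pixels)

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice %d x %d, scale=%s, stage=%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$scale, x$stage))
  invisible(x)
}

#' Convert a slice to the unit-interval float scale
#'
#' @param x An `image_slice`.
#' @return An `image_slice` on the `"unit"` scale; the stage tag is kept.
#' @export
as_unit_scale <- function(x) {
  stopifnot(inherits(x, "image_slice"))
  if (x$scale == "unit") return(x)
  x$pixels <- x$pixels / 255
  x$scale <- "unit"
  x
}

#' Convert a slice to the 8-bit integer scale
#'
#' Intensities are scaled by 255 and rounded to the nearest integer.
#'
#' @param x An `image_slice`.
#' @return An `image_slice` on the `"uint8"` scale; the stage tag is kept.
#' @export
as_uint8_scale <- function(x) {
  stopifnot(inherits(x, "image_slice"))
  if (x$scale == "uint8") return(x)
  x$pixels <- round(x$pixels * 255)
  x$scale <- "uint8"
  x
}

# replace pixel data, keeping range legal by clipping to the declared scale
set_pixels <- function(x, pixels, stage = x$stage) {
  lim <- if (x$scale == "unit") c(0, 1) else c(0, 255)
  pixels <- pmin(pmax(pixels, lim[1]), lim[2])
  x$pixels <- pixels
  x$stage <- stage
  x
}
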