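#' An ordered collection of labeled slices
#'
#' Pairs each `image_slice` with an integer class label (1-based index into
#' `class_names`). The canonical class order for the dementia-severity task
#' is [gfd_classes()]: NonDemented, VeryMildDemented, MildDemented,
#' ModerateDemented.
#'
#' @param slices List of `image_slice` objects.
#' @param labels Integer vector, same length, values in `1..length(class_names)`.
#' @param class_names Character vector of class names in label order.
#' @return A `labeled_dataset`.
#' @export
labeled_dataset <- function(slices, labels, class_names = gfd_classes()) {
  labels <- as.integer(labels)
  if (length(slices) != length(labels))
    stop("`slices` and `labels` must have equal length", call. = FALSE)
  if (length(labels) && (min(labels) < 1L || max(labels) > length(class_names)))
    stop("labels must index into `class_names`", call. = FALSE)
  structure(list(slices = slices, labels = labels, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$slices)

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset: %d slices, %d classes>\n",
              length(x$slices), length(x$class_names)))
  if (length(x$slices)) {
    tab <- tabulate(x$labels, nbins = length(x$class_names))
    for (i in seq_along(x$class_names))
      cat(sprintf("  %-18s %d\n", x$class_names[i], tab[i]))
  }
  invisible(x)
}

#' Subset a labeled dataset by position
#'
#' @param ds A `labeled_dataset`.
#' @param idx Integer positions to keep.
#' @return A `labeled_dataset` with the selected items, classes unchanged.
#' @export
dataset_subset <- function(ds, idx) {
  labeled_dataset(ds$slices[idx], ds$labels[idx], ds$class_names)
}

#' Per-class sample counts
#'
#' @param ds A `labeled_dataset`.
#' @return Named integer vector, one entry per class.
#' @export
class_counts <- function(ds) {
  n <- tabulate(ds$labels, nbins = length(ds$class_names))
  names(n) <- ds$class_names
  n
}

#' Read a class-per-subdirectory image dataset
#'
#' Expects the layout of the public dementia-MRI collections: one
#' subdirectory per class containing grayscale PNG (or JPEG-decoded PNG)
#' slices. Subdirectory names must match `class_names`; classes missing a
#' directory contribute zero slices.
#'
#' @param dir Dataset root directory.
#' @param class_names Class order; defaults to [gfd_classes()].
#' @return A `labeled_dataset` of raw unit-scale slices.
#' @export
read_dataset <- function(dir, class_names = gfd_classes()) {
  slices <- list(); labels <- integer()
  for (ci in seq_along(class_names)) {
    sub <- file.path(dir, class_names[ci])
    if (!dir.exists(sub)) next
    files <- sort(list.files(sub, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    for (f in files) {
      slices[[length(slices) + 1L]] <- read_slice(f)
      labels <- c(labels, ci)
    }
  }
  labeled_dataset(slices, labels, class_names)
}

#' Write a labeled dataset as class-subdirectory PNGs
#'
#' @param ds A `labeled_dataset`.
#' @param dir Output root; class subdirectories are created as needed.
#' @param manifest Optional path of a CSV manifest (`path,label`) to write.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  counters <- integer(length(ds$class_names))
  paths <- character(length(ds$slices))
  for (i in seq_along(ds$slices)) {
    ci <- ds$labels[i]
    sub <- file.path(dir, ds$class_names[ci])
    dir.create(sub, showWarnings = FALSE)
    counters[ci] <- counters[ci] + 1L
    paths[i] <- file.path(sub, sprintf("slice_%04d.png", counters[ci]))
    write_slice(ds$slices[[i]], paths[i])
  }
  if (!is.null(manifest))
    write.csv(data.frame(path = paths, label = ds$class_names[ds$labels]),
              manifest, row.names = FALSE)
  invisible(dir)
}

#' Read / write a single grayscale slice as PNG
#'
#' PNG stores images row-major from the top-left; slices are H x W matrices
#' on the unit scale. Multi-channel PNGs are collapsed to grayscale by
#' averaging the color channels.
#'
#' @param path PNG file path.
#' @return `read_slice`: an `image_slice` (unit scale, stage `"raw"`).
#' @export
read_slice <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  image_slice(px, scale = "unit", stage = "raw")
}

#' @rdname read_slice
#' @param img An `image_slice` (converted to unit scale for writing).
#' @return `write_slice`: `path`, invisibly.
#' @export
write_slice <- function(img, path) {
  u <- as_unit_scale(img)
  png::writePNG(pmin(pmax(u$pixels, 0), 1), path)
  invisible(path)
}
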