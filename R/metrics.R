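#' Confusion matrix from predicted and true labels
#'
#' @param pred,truth Equal-length integer vectors of class labels in `1..C`.
#' @param C Number of classes.
#' @return C x C integer matrix of class `confusion_matrix`; rows are the
#'   true class, columns the predicted class.
#' @examples
#' confusion(c(1, 2, 2, 2), c(1, 1, 2, 2), C = 2)
#' @export
confusion <- function(pred, truth, C) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) && (min(c(pred, truth)) < 1L || max(c(pred, truth)) > C))
    stop(sprintf("labels must lie in 1..%d", C), call. = FALSE)
  cm <- matrix(0L, C, C)
  for (i in seq_along(pred))
    cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("confusion matrix must be square and non-negative", call. = FALSE)
  if (sum(cm) == 0)
    stop("metrics are undefined for an empty confusion matrix",
         call. = FALSE)
  invisible(cm)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Accuracy is the trace over the total. For a 2x2 matrix (class 1 taken as
#' negative, class 2 as positive) sensitivity is `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)`. For C > 2 both are unweighted macro
#' averages of the per-class one-vs-rest values; a class with a zero
#' denominator (no samples of that class, so recall is undefined) is
#' skipped from the macro mean with a warning.
#'
#' @param cm A square confusion matrix with at least one count.
#' @return Scalar in \[0, 1\].
#' @examples
#' cm <- rbind(c(9, 1), c(2, 8))   # TN=9 FP=1 / FN=2 TP=8
#' accuracy(cm); sensitivity(cm); specificity(cm)
#' @export
accuracy <- function(cm) {
  check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

one_vs_rest <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

macro_rate <- function(cm, num_of, den_of, what) {
  C <- nrow(cm)
  vals <- numeric(0)
  skipped <- character(0)
  for (k in seq_len(C)) {
    o <- one_vs_rest(cm, k)
    den <- den_of(o)
    if (den == 0) { skipped <- c(skipped, as.character(k)); next }
    vals <- c(vals, num_of(o) / den)
  }
  if (length(skipped))
    warning(sprintf("%s undefined for class(es) %s; skipped from macro mean",
                    what, paste(skipped, collapse = ", ")), call. = FALSE)
  mean(vals)
}

#' @rdname accuracy
#' @export
sensitivity <- function(cm) {
  check_cm(cm)
  if (nrow(cm) == 2L) {
    o <- one_vs_rest(cm, 2L)
    return(o[["tp"]] / (o[["tp"]] + o[["fn"]]))
  }
  macro_rate(cm, function(o) o[["tp"]], function(o) o[["tp"]] + o[["fn"]],
             "sensitivity")
}

#' @rdname accuracy
#' @export
specificity <- function(cm) {
  check_cm(cm)
  if (nrow(cm) == 2L) {
    o <- one_vs_rest(cm, 2L)
    return(o[["tn"]] / (o[["tn"]] + o[["fp"]]))
  }
  macro_rate(cm, function(o) o[["tn"]], function(o) o[["tn"]] + o[["fp"]],
             "specificity")
}

#' Per-class one-vs-rest recall
#'
#' @param cm A confusion matrix.
#' @return Numeric vector of length C; `NA` for classes with no true
#'   samples.
#' @export
per_class_recall <- function(cm) {
  check_cm(cm)
  vapply(seq_len(nrow(cm)), function(k) {
    o <- one_vs_rest(cm, k)
    if (o[["tp"]] + o[["fn"]] == 0) NA_real_
    else o[["tp"]] / (o[["tp"]] + o[["fn"]])
  }, numeric(1))
}

#' Bundle the evaluation metrics of a confusion matrix
#'
#' @param cm A confusion matrix.
#' @param class_names Optional class names for the per-class block.
#' @return List with `accuracy`, `sensitivity`, `specificity`, `per_class`
#'   (one-vs-rest recall per class) and the raw `confusion` counts.
#' @export
metrics_report <- function(cm, class_names = NULL) {
  check_cm(cm)
  pc <- per_class_recall(cm)
  if (!is.null(class_names)) names(pc) <- class_names
  list(accuracy = accuracy(cm),
       sensitivity = suppressWarnings(sensitivity(cm)),
       specificity = suppressWarnings(specificity(cm)),
       per_class = as.list(pc),
       confusion = unclass(cm))
}

#' Write a metrics report as JSON and CSV
#'
#' @param report A [metrics_report()].
#' @param json_path,csv_path Output paths; either may be `NULL` to skip.
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  if (!is.null(csv_path)) {
    flat <- data.frame(metric = c("accuracy", "sensitivity", "specificity"),
                       value = c(report$accuracy, report$sensitivity,
                                 report$specificity))
    write.csv(flat, csv_path, row.names = FALSE)
  }
  invisible(report)
}
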