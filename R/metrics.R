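# Multi-class classification metrics and the mean relative error used to
# score the pipeline against labeled data.

#' Confusion matrix of two label vectors
#'
#' @param actual,predicted equal-length label vectors; rows of the result
#'   are actual classes, columns predicted classes.
#' @param labels the declared class set; defaults to the sorted union of
#'   the observed labels. Declared but unseen classes appear as zero
#'   rows/columns; labels outside the declared set are an error.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted, labels = NULL) {
  if (length(actual) != length(predicted) || !length(actual)) {
    stopf("actual and predicted must have equal positive length")
  }
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (is.null(labels)) {
    labels <- sort(unique(c(actual, predicted)))
  } else {
    labels <- as.character(labels)
    unknown <- setdiff(unique(c(actual, predicted)), labels)
    if (length(unknown)) stopf("unknown label %s", unknown[[1L]])
  }
  cm <- table(
    factor(actual, levels = labels),
    factor(predicted, levels = labels)
  )
  m <- matrix(as.integer(cm), nrow = length(labels),
              dimnames = list(actual = labels, predicted = labels))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (rows = actual, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy, per-class precision/recall/F1 and Cohen's kappa
#'
#' One-vs-rest reduction of the binary definitions: for each class c,
#' `TP = cm[c,c]`, `FP = colsum - TP`, `FN = rowsum - TP`, giving
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)` and the harmonic-mean
#' F1. Overall accuracy is `trace/total`; Cohen's kappa is
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = accuracy` and
#' chance agreement `p_e = sum(rowsum * colsum) / total^2`.
#'
#' A class with zero predicted and zero actual instances has undefined
#' precision and recall; these are reported as `NA` with the `undefined`
#' flag set and excluded from the macro averages rather than being coerced
#' to zero.
#'
#' @param cm a [confusion()] matrix (or any square counts matrix).
#' @return An object of class `classification_metrics`: list with
#'   `accuracy`, `kappa`, `p_o`, `p_e`, `per_class` (data frame with
#'   `precision`, `recall`, `f1`, `undefined`), and macro averages
#'   `macro_precision`, `macro_recall`, `macro_f1`.
#' @export
classification_metrics <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m)) stopf("confusion matrix must be square")
  total <- sum(m)
  if (total <= 0) stopf("confusion matrix is empty")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  tp <- diag(m)
  rowt <- rowSums(m)
  colt <- colSums(m)
  precision <- ifelse(colt > 0, tp / colt, NA_real_)
  recall <- ifelse(rowt > 0, tp / rowt, NA_real_)
  f1 <- ifelse(
    !is.na(precision) & !is.na(recall) & (precision + recall) > 0,
    2 * precision * recall / (precision + recall),
    ifelse(is.na(precision) | is.na(recall), NA_real_, 0)
  )
  undefined <- rowt == 0 & colt == 0
  p_o <- sum(tp) / total
  p_e <- sum(rowt * colt) / total^2
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else 0
  per_class <- data.frame(
    class = labels, precision = precision, recall = recall, f1 = f1,
    undefined = undefined, row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      accuracy = p_o, kappa = kappa, p_o = p_o, p_e = p_e,
      per_class = per_class,
      macro_precision = mean(precision[!undefined], na.rm = TRUE),
      macro_recall = mean(recall[!undefined], na.rm = TRUE),
      macro_f1 = mean(f1[!undefined], na.rm = TRUE)
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "Accuracy %.4f, Cohen's kappa %.4f (p_o %.4f, p_e %.4f)\n",
    x$accuracy, x$kappa, x$p_o, x$p_e
  ))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean relative error of paired measurements
#'
#' `MRE = 100/N * sum(|measured_i - reference_i| / reference_i)` in
#' percent; the standard index for comparing algorithmic ATR measurements
#' with clinician readings.
#'
#' @param measured,reference equal-length numeric vectors; all reference
#'   values must be nonzero.
#' @return MRE in percent.
#' @export
mean_relative_error <- function(measured, reference) {
  if (length(measured) != length(reference) || !length(measured)) {
    stopf("measured and reference must have equal positive length")
  }
  zero <- which(reference == 0)
  if (length(zero)) {
    stopf("reference value at index %d is zero", zero[[1L]])
  }
  100 * mean(abs(measured - reference) / abs(reference))
}
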