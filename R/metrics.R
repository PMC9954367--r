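#' Pixel-level confusion counts
#'
#' Every evaluated pixel of the tumorous area contributes one unit; the
#' positive class is high cellularity (ADC below the cut-off).
#'
#' @param pred,truth equal-length binary (0/1) label vectors.
#' @return Named numeric vector with elements TP, FP, TN, FN.
#' @export
confusionCounts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 length(pred), length(truth)))
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("labels must be binary 0/1")
  c(TP = sum(pred == 1 & truth == 1),
    FP = sum(pred == 1 & truth == 0),
    TN = sum(pred == 0 & truth == 0),
    FN = sum(pred == 0 & truth == 1))
}

#' Classification metrics from confusion counts
#'
#' Accuracy is correct predictions over all predictions; sensitivity
#' (recall of the positive class) is TP / (TP + FN); specificity is
#' TN / (TN + FP); balanced accuracy is the mean of the two class recalls.
#' A metric with a zero denominator is reported as NA (missing), never
#' NaN, and is excluded from cohort averages downstream.
#'
#' @param counts output of \code{\link{confusionCounts}}.
#' @return Named numeric vector: accuracy, balanced_accuracy, sensitivity,
#'   specificity.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("no evaluated pixels")
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  bal <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  c(accuracy = (tp + tn) / total,
    balanced_accuracy = bal,
    sensitivity = sens,
    specificity = spec)
}
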