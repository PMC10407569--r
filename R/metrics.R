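#' Confusion matrix from labels and predictions
#'
#' @param labels true binary labels (0/1; 1 = positive class).
#' @param predicted predicted binary labels.
#' @return list of class `confusion_matrix` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_matrix <- function(labels, predicted) {
  stopifnot(length(labels) == length(predicted),
            all(labels %in% c(0, 1)), all(predicted %in% c(0, 1)))
  structure(list(tp = sum(labels == 1 & predicted == 1),
                 fp = sum(labels == 0 & predicted == 1),
                 fn = sum(labels == 1 & predicted == 0),
                 tn = sum(labels == 0 & predicted == 0)),
            class = "confusion_matrix")
}

#' F-score (harmonic mean of precision and recall)
#'
#' @param precision,recall numeric values in \[0, 1\].
#' @return the F1 score, or `NA` when precision + recall is 0.
#' @export
f_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, recall (sensitivity), precision, F-score and the
#' Matthews correlation coefficient. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion_matrix()].
#' @return list with elements `accuracy`, `recall`, `precision`, `f_score`,
#'   `mcc`.
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  n <- tp + fp + fn + tn
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(accuracy = safe_div(tp + tn, n),
       recall = recall,
       precision = precision,
       mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else NA_real_,
       f_score = f_score(precision, recall))
}

#' ROC curve and AUC
#'
#' Sweeps every observed score threshold to trace the ROC curve and
#' integrates it by the trapezoid rule, so tied scores contribute half
#' credit: the AUC equals the probability that a random positive outscores
#' a random negative.
#'
#' @param labels true binary labels (both classes must be present).
#' @param scores real-valued decision scores (higher = more positive).
#' @return list with `roc` (tibble of `threshold`, `fpr`, `tpr`, beginning
#'   at (0, 0)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single thresholds
  last <- cumsum(rle(sc)$lengths)
  tpr <- cumsum(lab == 1)[last] / n_pos
  fpr <- cumsum(lab == 0)[last] / n_neg
  roc <- tibble::tibble(threshold = c(Inf, sc[last]),
                        fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  list(roc = roc, auc = auc)
}
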