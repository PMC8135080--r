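#' Confusion matrix at a probability threshold
#'
#' @param probs predicted probabilities of the positive class.
#' @param labels logical (or 0/1) actual labels, `TRUE` = positive.
#' @param threshold classification cutoff; predicted positive when
#'   `prob >= threshold`.
#' @return A list of class `confusion_matrix` with integer `TP`, `FP`, `TN`,
#'   `FN`.
#' @export
confusion_matrix <- function(probs, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  stopifnot(length(probs) == length(labels), !anyNA(probs), !anyNA(labels))
  pred <- probs >= threshold
  structure(list(TP = sum(pred & labels), FP = sum(pred & !labels),
                 TN = sum(!pred & !labels), FN = sum(!pred & labels)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x$TP, x$FP, x$TN, x$FN, x$TP + x$FP + x$TN + x$FN))
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps the unique score values as thresholds (descending) and records
#' (FPR, TPR) at each; tied scores move as a block, so the trapezoidal area
#' gives ties half credit, making the area equal to the pairwise-concordance
#' (Mann-Whitney) statistic.
#'
#' @inheritParams confusion_matrix
#' @return A data frame with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(probs, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) fail("need both classes for a ROC curve")
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]; l_sorted <- labels[ord]
  block_end <- c(which(diff(p_sorted) != 0), length(p_sorted))
  tp <- cumsum(l_sorted)[block_end]
  fp <- cumsum(!l_sorted)[block_end]
  data.frame(
    threshold = c(Inf, p_sorted[block_end]),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
}

#' Precision-recall curve by threshold sweep
#'
#' @inheritParams confusion_matrix
#' @return A data frame with columns `threshold`, `recall`, `precision`,
#'   anchored at recall 0 and reaching recall 1 (precision = prevalence floor
#'   at the lowest threshold).
#' @export
pr_curve <- function(probs, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) fail("need positives for a PR curve")
  ord <- order(probs, decreasing = TRUE)
  p_sorted <- probs[ord]; l_sorted <- labels[ord]
  block_end <- c(which(diff(p_sorted) != 0), length(p_sorted))
  tp <- cumsum(l_sorted)[block_end]
  prec <- tp / block_end
  rec <- tp / n_pos
  data.frame(threshold = c(Inf, p_sorted[block_end]),
             recall = c(0, rec),
             precision = c(prec[1], prec))
}

#' Trapezoidal area under the ROC curve
#' @param roc a [roc_curve()] data frame.
#' @return Area in \[0, 1\].
#' @export
auc_trapezoid <- function(roc) {
  dx <- diff(roc$fpr)
  sum(dx * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Step-rule area under the precision-recall curve
#'
#' Non-interpolated rule: `sum over i of (R_i - R_{i-1}) * P_i` across
#' descending thresholds (the scikit-learn average-precision convention).
#' @param pr a [pr_curve()] data frame.
#' @return Area in \[0, 1\].
#' @export
auc_pr_step <- function(pr) {
  sum(diff(pr$recall) * pr$precision[-1])
}

#' Classification metric set from pooled probabilities
#'
#' Computes the published metric formulas at the given threshold: accuracy,
#' recall (= true positive rate, TP/(TP+FN)), false positive rate
#' (FP/(FP+TN)), precision (TP/(TP+FP)), F1 (harmonic mean of precision and
#' recall), plus the two curve areas. When a ratio's denominator is zero the
#' metric is `NaN`; constant score vectors yield AUC 0.5 (pure ties) with a
#' warning.
#'
#' @inheritParams confusion_matrix
#' @return A list of class `metric_set` with fields `accuracy`, `recall`,
#'   `fpr`, `precision`, `f1`, `auc_roc`, `auc_pr` and the `confusion` matrix.
#' @export
metric_set <- function(probs, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  cm <- confusion_matrix(probs, labels, threshold)
  n <- cm$TP + cm$FP + cm$TN + cm$FN
  ratio <- function(num, den) if (den == 0) NaN else num / den
  precision <- ratio(cm$TP, cm$TP + cm$FP)
  recall <- ratio(cm$TP, cm$TP + cm$FN)
  f1 <- if (is.nan(precision) || is.nan(recall) || precision + recall == 0)
    NaN else 2 * precision * recall / (precision + recall)
  if (length(unique(probs)) == 1)
    warning("constant pooled probabilities; AUC defined as 0.5")
  structure(list(
    accuracy = (cm$TP + cm$TN) / n,
    recall = recall,
    fpr = ratio(cm$FP, cm$FP + cm$TN),
    precision = precision,
    f1 = f1,
    auc_roc = auc_trapezoid(roc_curve(probs, labels)),
    auc_pr = auc_pr_step(pr_curve(probs, labels)),
    confusion = cm
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | recall %.3f | precision %.3f | F1 %.3f | AUCROC %.3f | AUCPR %.3f\n",
    x$accuracy, x$recall, x$precision, x$f1, x$auc_roc, x$auc_pr))
  invisible(x)
}
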