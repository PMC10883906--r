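#' F1 score from precision and recall
#'
#' Harmonic mean `2 p r / (p + r)`; `NA` when both are zero or either is
#' undefined.
#'
#' @param precision,recall values in `[0, 1]`
#' @return F1 in `[0, 1]` or `NA`
#' @export
#' @examples
#' round(f1_score(0.734, 0.611), 3) # 0.667
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
    return(NA_real_)
  }
  2 * precision * recall / (precision + recall)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator with midrank tie handling.
#'
#' @param scores numeric scores, larger = more positive
#' @param labels 0/1 vector
#' @return AUROC in `[0, 1]`, `NA` if a class is absent
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise AUPRC)
#'
#' The step-wise estimator `sum_k (R_k - R_{k-1}) P_k` over distinct score
#' thresholds in decreasing order -- no trapezoidal interpolation, which
#' would inflate the area on imbalanced data. Tied scores enter at a single
#' threshold. A constant scorer therefore yields the positive prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`, `NA` if a class is absent
#' @export
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  P <- sum(labels == 1L)
  if (P == 0L || all(labels == 1L)) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- which(s != c(s[-1L], NA) | seq_along(s) == length(s)) # threshold ends
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a classifier on a labeled dataset
#'
#' Thresholded metrics use the argmax of the two output scores (equivalent
#' to 0.5 on the softmax positive probability); AUROC and AUPRC use the
#' positive-class probability. On single-class data the ranking metrics are
#' reported as `NA` with a warning while the thresholded metrics are still
#' computed.
#'
#' @param model a trained `crisproff_model`
#' @param data data.frame with `sgrna`, `dna`, `label`
#' @return object of class `metrics_report`: accuracy, precision, recall,
#'   f1, auroc, auprc and the TP/FP/TN/FN counts
#' @export
evaluate <- function(model, data) {
  stopifnot(all(c("sgrna", "dna", "label") %in% names(data)))
  probs <- predict(model, data, type = "prob")
  scores <- probs[, 2L]
  labels <- as.integer(data$label)
  pred <- as.integer(scores > probs[, 1L])
  metrics_report(scores, pred, labels)
}

#' @rdname evaluate
#' @param scores positive-class scores
#' @param pred 0/1 predicted classes
#' @param labels 0/1 true labels
#' @export
metrics_report <- function(scores, pred, labels) {
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  precision <- if ((tp + fp) > 0L) tp / (tp + fp) else NA_real_
  recall <- if ((tp + fn) > 0L) tp / (tp + fn) else NA_real_
  if (length(unique(labels)) < 2L) {
    warning("single-class data: AUROC/AUPRC undefined", call. = FALSE)
  }
  structure(list(
    accuracy = (tp + tn) / length(labels),
    precision = precision,
    recall = recall,
    f1 = f1_score(precision, recall),
    auroc = auroc(scores, labels),
    auprc = average_precision(scores, labels),
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<classification metrics>\n")
  for (nm in c("accuracy", "precision", "recall", "f1", "auroc", "auprc")) {
    cat(sprintf("  %-9s %s\n", nm,
                ifelse(is.na(x[[nm]]), "NA", sprintf("%.4f", x[[nm]]))))
  }
  cat(sprintf("  counts    TP=%d FP=%d TN=%d FN=%d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  invisible(x)
}
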