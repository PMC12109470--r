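#' @include AllClasses.R
NULL

#' Confusion-matrix metrics
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, recall `TP/(TP+FN)` and F1 (harmonic
#' mean of precision and recall). Recall with `TP + FN = 0` is reported as
#' `NA` (undefined); F1 with zero precision and recall is 0.
#'
#' @param tp,fp,tn,fn non-negative confusion counts (MDD is the positive
#'   class); the four must not all be zero.
#' @return named numeric: `accuracy`, `recall`, `precision`, `f1`.
#' @examples
#' confusionMetrics(tp = 8, fp = 1, tn = 9, fn = 2)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  tp <- unname(tp); fp <- unname(fp); tn <- unname(tn); fn <- unname(fn)
  counts <- c(tp, fp, tn, fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("confusion counts are all zero")
  acc <- (tp + tn) / sum(counts)
  rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (is.na(rec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, recall = rec, precision = prec, f1 = f1)
}

#' Rank-based ROC AUC
#'
#' The probability that a random positive outranks a random negative,
#' with ties counting one half — identical to trapezoidal integration of
#' the ROC curve.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (1/`"MDD"` positive); both classes must be
#'   present.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, labels) {
  y <- .asBinaryLabel(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
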