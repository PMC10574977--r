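#' Confusion counts
#'
#' @param tp,fp,fn,tn non-negative integer counts; at least one positive.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  cnt <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  if (sum(cnt) == 0) stop("all counts are zero")
  structure(as.list(cnt), class = "confusion_counts")
}

# counts from scores + labels at a decision threshold (s >= t -> positive)
counts_at_threshold <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  confusion_counts(tp = sum(pred == 1 & labels == 1),
                   fp = sum(pred == 1 & labels == 0),
                   fn = sum(pred == 0 & labels == 1),
                   tn = sum(pred == 0 & labels == 0))
}

#' Per-class performance metrics from a confusion matrix
#'
#' Computes positive/negative precision, positive/negative sensitivity
#' (recall), PPV (identical to positive precision), accuracy, and the
#' positive-class F1. A metric whose denominator is zero is returned as
#' `NA` and listed in the `undefined` attribute rather than fabricated.
#'
#' @param counts a [confusion_counts()] object.
#' @return named list of class `metrics_report`; all defined values lie
#'   in `[0, 1]`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  rep <- list(
    precision_pos = div(tp, tp + fp),
    precision_neg = div(tn, tn + fn),
    sensitivity_pos = div(tp, tp + fn),
    sensitivity_neg = div(tn, tn + fp),
    ppv = div(tp, tp + fp),
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    f1_pos = div(2 * tp, 2 * tp + fp + fn))
  attr(rep, "undefined") <- names(rep)[vapply(rep, is.na, logical(1))]
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- unlist(x)
  cat(sprintf("%-16s %s\n", names(v), formatC(v, digits = digits, format = "f")),
      sep = "")
  invisible(x)
}

#' Exact ROC AUC via the Mann-Whitney statistic
#'
#' The probability that a random positive outscores a random negative,
#' with ties counted half: computed from average ranks, which is exactly
#' the pairwise Mann-Whitney U estimator (no trapezoidal approximation).
#'
#' @param scores numeric vector.
#' @param labels 0/1 vector with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)             # average ranks give half-credit ties
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}
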