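#' Trust-scoring parameters
#'
#' @param alpha reward relaxation coefficient (`>= 0`).
#' @param beta penalty relaxation coefficient (`>= 0`).
#' @param threshold decision threshold in (0, 1); scores `>= threshold`
#'   are predicted positive.
#' @return an object of class `trust_params`.
#' @export
trust_params <- function(alpha = 1, beta = 1, threshold = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, threshold > 0, threshold < 1)
  structure(list(alpha = alpha, beta = beta, threshold = threshold),
            class = "trust_params")
}

#' F1-optimal decision threshold
#'
#' Exhaustively searches the finite set of thresholds that can change the
#' classification — midpoints between consecutive distinct sorted scores,
#' plus the boundary candidates `min(s)/2` and `(1 + max(s))/2` — and
#' returns the one maximizing positive-class F1 under the rule
#' `score >= t` implies positive. Among ties the smallest candidate wins,
#' favoring sensitivity for the minority class.
#'
#' @param scores validation scores in (0, 1).
#' @param labels 0/1 validation labels; both classes must be present.
#' @return the selected threshold, with attribute `"f1"` giving its F1.
#' @export
select_threshold <- function(scores, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("both classes must be present to calibrate a threshold")
  u <- sort(unique(scores))
  cand <- c(u[1] / 2,
            if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            (1 + u[length(u)]) / 2)
  f1 <- vapply(cand, function(t) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + sum(pred & labels == 0) + sum(!pred & labels == 1))
  }, numeric(1))
  best <- cand[which.max(f1)]   # which.max returns the first (smallest) maximizer
  structure(best, f1 = max(f1))
}

#' Normalize a raw score into a decision-aware confidence scale
#'
#' Piecewise-linear, continuous and strictly increasing map anchored at
#' the theoretical sigmoid score range: scores below the threshold (the
#' negative prediction region) map onto `(0, 0.5)`, scores at or above it
#' (positive predictions) onto `[0.5, 1)`, with `p(t) = 0.5` exactly. The
#' anchoring at 0 and 1 (rather than the observed score range) keeps the
#' map dataset-independent.
#'
#' @param s raw score(s) in (0, 1); vectorized.
#' @param t decision threshold in (0, 1).
#' @return normalized value(s) `p` in `[0, 1]`.
#' @export
normalize_confidence <- function(s, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t >= 1)
    stop("threshold must be a single number strictly inside (0, 1)")
  ifelse(s < t, 0.5 * s / t, 0.5 + 0.5 * (s - t) / (1 - t))
}

#' Question-answer trust of a single answer
#'
#' Rewards deserved confidence and penalizes undeserved confidence:
#' `Q = C^alpha` when the model's answer is correct and
#' `Q = (1 - C)^beta` when it is wrong, where `C` is the model's
#' confidence in the answer it gave. With `alpha = beta = 0` the score
#' degenerates to 1 everywhere.
#'
#' @param C confidence in the given answer, in `[0, 1]`; vectorized.
#' @param correct logical, whether the answer matches the truth; recycled
#'   against `C`.
#' @param alpha,beta reward/penalty relaxation coefficients (`>= 0`).
#' @return trust value(s) `Q` in `[0, 1]`.
#' @export
qa_trust <- function(C, correct, alpha = 1, beta = 1) {
  if (any(C < 0 | C > 1)) stop("confidence must lie in [0, 1]")
  stopifnot(alpha >= 0, beta >= 0)
  ifelse(correct, C^alpha, (1 - C)^beta)
}

#' Positive-class trust score of a model
#'
#' Applies the full question-answer trust pipeline to a prediction table:
#' each sample's predicted answer is assigned by the threshold, its raw
#' score is normalized into `[0, 1]`, confidence in the given answer is
#' `C = p` for positive answers and `C = 1 - p` for negative answers, and
#' per-sample trust follows [qa_trust()]. The headline score is the mean
#' trust over the ground-truth-positive samples; the symmetric
#' negative-class mean is also reported.
#'
#' @param records data frame with columns `id`, `raw_score` (in (0, 1))
#'   and `true_label` (0/1), containing at least one true positive.
#' @param params a [trust_params()] carrying the calibrated threshold.
#' @return an object of class `trust_report`: list with `per_sample`
#'   (data frame `id`, `true_label`, `predicted`, `confidence`, `Q`),
#'   `positive_trust`, `negative_trust`, `n_positive`, and the parameters
#'   used.
#' @export
positive_trust_score <- function(records, params = trust_params()) {
  stopifnot(inherits(params, "trust_params"),
            all(c("id", "raw_score", "true_label") %in% names(records)))
  z <- as.integer(records$true_label)
  if (!any(z == 1)) stop("no ground-truth-positive samples to score")
  s <- records$raw_score
  y <- as.integer(s >= params$threshold)
  p <- normalize_confidence(s, params$threshold)
  C <- ifelse(y == 1L, p, 1 - p)
  Q <- qa_trust(C, y == z, params$alpha, params$beta)
  per <- data.frame(id = as.character(records$id), true_label = z,
                    predicted = y, confidence = C, Q = Q,
                    stringsAsFactors = FALSE)
  structure(list(per_sample = per,
                 positive_trust = mean(Q[z == 1L]),
                 negative_trust = if (any(z == 0L)) mean(Q[z == 0L]) else NA_real_,
                 n_positive = sum(z == 1L), params = params),
            class = "trust_report")
}

#' @export
print.trust_report <- function(x, ...) {
  cat("<trust_report> positive-class trust ",
      formatC(x$positive_trust, digits = 3, format = "f"),
      " over ", x$n_positive, " true positives (threshold ",
      formatC(x$params$threshold, digits = 3, format = "f"), ")\n", sep = "")
  invisible(x)
}

#' Write a trust report to disk
#'
#' Emits `trust.json` (threshold, coefficients, headline scores) and
#' `trust_per_sample.csv` (`id,Q`) under `out_dir`.
#'
#' @param report a `trust_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_trust_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(threshold = report$params$threshold, alpha = report$params$alpha,
         beta = report$params$beta, positive_trust = report$positive_trust,
         negative_trust = report$negative_trust, n_positive = report$n_positive),
    file.path(out_dir, "trust.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$per_sample[, c("id", "Q")],
                   file.path(out_dir, "trust_per_sample.csv"), row.names = FALSE)
  invisible(out_dir)
}
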