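#' State of the AUC min-max margin surrogate
#'
#' The deep-AUC margin surrogate replaces the non-differentiable ROC AUC
#' with a saddle-point objective over two primal auxiliary scalars `a`
#' and `b` (running surrogates for the mean positive and mean negative
#' score) and a non-negative dual variable `alpha`, with a fixed margin
#' `m` between the class score means:
#' \deqn{F = E_+[(h-a)^2] + E_-[(h-b)^2] + 2\alpha(m - E_+[h] + E_-[h]) - \alpha^2.}
#' Minimizing over the model and `(a, b)` while maximizing over
#' `alpha >= 0` drives positive scores above negative ones by the margin.
#' State persists across batches during stochastic optimization.
#'
#' @param a,b primal auxiliary variables.
#' @param alpha non-negative dual variable.
#' @param margin margin `m > 0`, fixed within a run.
#' @return an object of class `auc_margin_state`.
#' @export
auc_margin_state <- function(a = 0, b = 0, alpha = 0, margin = 1) {
  stopifnot(margin > 0, alpha >= 0)
  structure(list(a = a, b = b, alpha = alpha, margin = margin),
            class = "auc_margin_state")
}

check_mixed_batch <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0 or 1")
  if (!any(labels == 1) || !any(labels == 0))
    stop("AUC margin loss needs at least one positive and one negative per batch")
}

#' AUC margin surrogate objective
#'
#' Evaluates the min-max margin surrogate on one mixed batch of sigmoid
#' scores. At the analytic primal optimum `a = mean(h+)`, `b = mean(h-)`
#' and dual optimum `alpha = max(0, m - mean(h+) + mean(h-))` the value
#' reduces to `Var(h+) + Var(h-) + max(0, m - mean(h+) + mean(h-))^2`
#' (population variances), a closed form the tests check against.
#'
#' @param scores numeric vector of scores in `[0, 1]`.
#' @param labels 0/1 vector; both classes must be present.
#' @param state an [auc_margin_state()].
#' @return the scalar objective value.
#' @export
auc_margin_objective <- function(scores, labels, state) {
  check_mixed_batch(labels)
  hp <- scores[labels == 1]; hn <- scores[labels == 0]
  mean((hp - state$a)^2) + mean((hn - state$b)^2) +
    2 * state$alpha * (state$margin - mean(hp) + mean(hn)) - state$alpha^2
}

#' Analytic gradients of the AUC margin surrogate
#'
#' @inheritParams auc_margin_objective
#' @return list with `dscores` (same length as `scores`), `da`, `db` and
#'   `dalpha`; in particular
#'   `dalpha = 2 (m - mean(h+) + mean(h-)) - 2 alpha`.
#' @export
auc_margin_grads <- function(scores, labels, state) {
  check_mixed_batch(labels)
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  hp <- scores[pos]; hn <- scores[!pos]
  ds <- numeric(length(scores))
  ds[pos] <- 2 * (hp - state$a) / np - 2 * state$alpha / np
  ds[!pos] <- 2 * (hn - state$b) / nn + 2 * state$alpha / nn
  list(dscores = ds,
       da = -2 * mean(hp - state$a),
       db = -2 * mean(hn - state$b),
       dalpha = 2 * (state$margin - mean(hp) + mean(hn)) - 2 * state$alpha)
}

#' Primal-dual stochastic gradient step on the surrogate state
#'
#' Descends the primal auxiliaries `(a, b)` and ascends the dual `alpha`,
#' then projects `alpha` back onto `[0, Inf)`. Model weights are updated
#' separately through the score gradients; this step touches only the
#' surrogate's own variables.
#'
#' @param state an [auc_margin_state()].
#' @param grads gradient list from [auc_margin_grads()].
#' @param lr_primal,lr_dual step sizes.
#' @return the updated `auc_margin_state`.
#' @export
pdsg_update <- function(state, grads, lr_primal, lr_dual) {
  if (!all(is.finite(c(grads$da, grads$db, grads$dalpha))))
    stop("non-finite gradient in primal-dual update (da=", grads$da,
         ", db=", grads$db, ", dalpha=", grads$dalpha, ")")
  state$a <- state$a - lr_primal * grads$da
  state$b <- state$b - lr_primal * grads$db
  state$alpha <- max(0, state$alpha + lr_dual * grads$dalpha)
  state
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log s + (1 - y) log(1 - s))` over the batch. Scores at
#' exactly 0 or 1 are clamped away from the boundary by `eps` (with a
#' warning) so the loss stays finite.
#'
#' @param scores sigmoid scores in `(0, 1)`.
#' @param labels 0/1 vector.
#' @param grad also return `dscores`.
#' @param eps boundary clamp.
#' @return the scalar loss, or `list(loss, dscores)` when `grad = TRUE`.
#' @export
cross_entropy <- function(scores, labels, grad = FALSE, eps = 1e-12) {
  if (any(scores <= 0 | scores >= 1)) {
    warning("scores at the (0, 1) boundary clamped by eps")
    scores <- pmin(pmax(scores, eps), 1 - eps)
  }
  n <- length(scores)
  loss <- -mean(labels * log(scores) + (1 - labels) * log(1 - scores))
  if (!grad) return(loss)
  list(loss = loss, dscores = (scores - labels) / (scores * (1 - scores)) / n)
}
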