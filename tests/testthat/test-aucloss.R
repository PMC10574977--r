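test_that("AUC margin objective matches hand-computed and closed-form values", {
  st <- auc_margin_state(a = 1, b = 0, alpha = 0, margin = 1)
  expect_equal(auc_margin_objective(c(1, 1, 0, 0), c(1, 1, 0, 0), st), 0)

  st2 <- auc_margin_state(a = 0.7, b = 0.3, alpha = 0.6, margin = 1)
  expect_equal(auc_margin_objective(c(0.8, 0.6, 0.2, 0.4), c(1, 1, 0, 0), st2),
               0.38, tolerance = 1e-12)

  # with alpha = 0 and (a, b) at the class means the objective is the sum
  # of within-class population variances
  set.seed(2)
  b <- random_mixed_batch(12)
  hp <- b$scores[b$labels == 1]; hn <- b$scores[b$labels == 0]
  st3 <- auc_margin_state(a = mean(hp), b = mean(hn), alpha = 0)
  expect_equal(auc_margin_objective(b$scores, b$labels, st3),
               mean((hp - mean(hp))^2) + mean((hn - mean(hn))^2),
               tolerance = 1e-12)

  expect_error(auc_margin_objective(c(0.1, 0.9), c(1, 1), st), "positive and")
})

test_that("objective at the analytic saddle equals its closed form on random batches", {
  set.seed(7)
  for (i in 1:100) {
    b <- random_mixed_batch(sample(4:30, 1))
    m <- runif(1, 0.2, 1.5)
    hp <- b$scores[b$labels == 1]; hn <- b$scores[b$labels == 0]
    st <- auc_margin_state(a = mean(hp), b = mean(hn),
                           alpha = max(0, m - mean(hp) + mean(hn)), margin = m)
    closed <- mean((hp - mean(hp))^2) + mean((hn - mean(hn))^2) +
      max(0, m - mean(hp) + mean(hn))^2
    expect_equal(auc_margin_objective(b$scores, b$labels, st), closed,
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match central finite differences", {
  set.seed(19)
  for (i in 1:20) {
    b <- random_mixed_batch(10)
    st <- auc_margin_state(a = runif(1), b = runif(1), alpha = runif(1),
                           margin = runif(1, 0.5, 1.5))
    g <- auc_margin_grads(b$scores, b$labels, st)
    eps <- 1e-5
    for (j in seq_along(b$scores)) {
      sp <- b$scores; sp[j] <- sp[j] + eps
      sm <- b$scores; sm[j] <- sm[j] - eps
      fd <- (auc_margin_objective(sp, b$labels, st) -
               auc_margin_objective(sm, b$labels, st)) / (2 * eps)
      expect_equal(g$dscores[j], fd, tolerance = 1e-4)
    }
    fd_part <- function(field) {
      stp <- st; stp[[field]] <- stp[[field]] + eps
      stm <- st; stm[[field]] <- stm[[field]] - eps
      (auc_margin_objective(b$scores, b$labels, stp) -
          auc_margin_objective(b$scores, b$labels, stm)) / (2 * eps)
    }
    expect_equal(g$da, fd_part("a"), tolerance = 1e-4)
    expect_equal(g$db, fd_part("b"), tolerance = 1e-4)
    expect_equal(g$dalpha, fd_part("alpha"), tolerance = 1e-4)
  }
  # stationarity at the analytic primal optimum; dalpha forced by the margin
  st <- auc_margin_state(a = 0.5, b = 0.5, alpha = 0, margin = 1)
  g <- auc_margin_grads(rep(0.5, 6), c(1, 1, 1, 0, 0, 0), st)
  expect_equal(g$da, 0); expect_equal(g$db, 0)
  expect_equal(g$dalpha, 2)
})

test_that("primal-dual updates project the dual and reach the batch optimum", {
  st <- auc_margin_state(a = 0.2, b = 0.1, alpha = 0.1, margin = 1)
  zero <- list(da = 0, db = 0, dalpha = 0)
  expect_identical(pdsg_update(st, zero, 0.1, 0.1), st)

  g <- list(da = 0, db = 0, dalpha = -4)
  expect_equal(pdsg_update(st, g, 0.1, 0.1)$alpha, 0)   # 0.1 - 0.4 projected

  expect_error(pdsg_update(st, list(da = NaN, db = 0, dalpha = 0), 0.1, 0.1),
               "non-finite")

  # repeated full-batch steps drive (a, b) to the class score means
  scores <- c(0.9, 0.7, 0.2, 0.3); labels <- c(1, 1, 0, 0)
  st <- auc_margin_state()
  for (i in 1:200)
    st <- pdsg_update(st, auc_margin_grads(scores, labels, st), 0.1, 0)
  expect_equal(st$a, 0.8, tolerance = 1e-3)
  expect_equal(st$b, 0.25, tolerance = 1e-3)

  # dual never leaves [0, Inf) over a noisy stochastic run
  set.seed(31)
  st <- auc_margin_state()
  for (i in 1:300) {
    b <- random_mixed_batch(8)
    st <- pdsg_update(st, auc_margin_grads(b$scores, b$labels, st), 0.05, 0.05)
    expect_gte(st$alpha, 0)
  }
})

test_that("cross-entropy matches hand expansion and boundary behavior", {
  expect_equal(cross_entropy(rep(0.5, 5), c(1, 0, 1, 0, 1)), log(2))
  expect_lt(cross_entropy(c(1 - 1e-9, 1e-9), c(1, 0)), 1e-6)
  set.seed(4)
  s <- runif(6, 0.05, 0.95); y <- rbinom(6, 1, 0.5)
  byhand <- -sum(y * log(s) + (1 - y) * log(1 - s)) / 6
  expect_equal(cross_entropy(s, y), byhand, tolerance = 1e-10)
  expect_warning(cross_entropy(c(0, 0.5), c(0, 1)), "clamp")
  # gradient consistency
  g <- cross_entropy(s, y, grad = TRUE)
  for (j in 1:6) {
    sp <- s; sp[j] <- sp[j] + 1e-6
    sm <- s; sm[j] <- sm[j] - 1e-6
    fd <- (cross_entropy(sp, y) - cross_entropy(sm, y)) / 2e-6
    expect_equal(g$dscores[j], fd, tolerance = 1e-5)
  }
})
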