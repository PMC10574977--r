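test_that("threshold selection equals brute-force F1 maximization", {
  t <- select_threshold(c(0.1, 0.2, 0.6, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(t), 0.4)
  expect_equal(attr(t, "f1"), 1)

  # inverted scorer: returned threshold still attains the brute-force best
  t2 <- select_threshold(c(0.9, 0.1), c(0, 1))
  expect_lt(attr(t2, "f1"), 1)
  expect_equal(attr(t2, "f1"), best_f1_bruteforce(c(0.9, 0.1), c(0, 1)))

  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    s <- runif(n)
    y <- c(1, 0, rbinom(n - 2, 1, runif(1, 0.1, 0.9)))
    t <- select_threshold(s, y)
    expect_equal(attr(t, "f1"), best_f1_bruteforce(s, y), tolerance = 1e-12)
    expect_equal(f1_at(s, y, as.numeric(t)), attr(t, "f1"), tolerance = 1e-12)
  }

  # separable case reaches F1 = 1; smallest maximizer wins ties
  s <- c(0.1, 0.2, 0.7, 0.8); y <- c(0, 0, 1, 1)
  expect_equal(attr(select_threshold(s, y), "f1"), 1)
  expect_equal(as.numeric(select_threshold(s, y)), 0.45)
  expect_error(select_threshold(c(0.2, 0.4), c(1, 1)), "both classes")
})

test_that("confidence normalization is anchored, continuous and strictly increasing", {
  expect_equal(normalize_confidence(0.3, 0.3), 0.5)
  expect_equal(normalize_confidence(0.15, 0.3), 0.25)
  expect_equal(normalize_confidence(1e-12, 0.7), 1e-12 / 1.4)
  expect_lt(abs(normalize_confidence(1 - 1e-12, 0.7) - 1), 1e-11)
  for (t in c(0.1, 0.37, 0.5, 0.9)) {
    g <- seq(1e-4, 1 - 1e-4, length.out = 10000)
    p <- normalize_confidence(g, t)
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 0 & p <= 1))
    # continuity at the knot
    expect_equal(normalize_confidence(t - 1e-10, t),
                 normalize_confidence(t, t), tolerance = 1e-8)
  }
  expect_error(normalize_confidence(0.5, 0), "inside")
  expect_error(normalize_confidence(0.5, 1), "inside")
})

test_that("question-answer trust follows the reward/penalty form", {
  expect_equal(qa_trust(1, TRUE, 1, 1), 1)
  expect_equal(qa_trust(1, FALSE, 1, 1), 0)
  expect_equal(qa_trust(0.9, TRUE, 2, 1), 0.81)
  # degenerate relaxation: alpha = beta = 0 gives Q = 1 everywhere
  C <- seq(0, 1, length.out = 11)
  expect_equal(qa_trust(C, rep(c(TRUE, FALSE), length.out = 11), 0, 0),
               rep(1, 11))
  # monotone in confidence: rising when correct, falling when wrong
  for (a in c(0.5, 1, 2)) {
    expect_true(all(diff(qa_trust(C, TRUE, alpha = a)) >= 0))
    expect_true(all(diff(qa_trust(C, FALSE, beta = a)) <= 0))
  }
  expect_error(qa_trust(1.2, TRUE), "\\[0, 1\\]")
})

test_that("positive trust score equals a scalar per-sample loop", {
  set.seed(12)
  n <- 1000
  rec <- data.frame(id = sprintf("p%04d", 1:n),
                    raw_score = runif(n, 1e-3, 1 - 1e-3),
                    true_label = rbinom(n, 1, 0.3))
  for (t in c(0.2, 0.5, 0.8)) {
    rep <- positive_trust_score(rec, trust_params(threshold = t))
    expect_equal(rep$positive_trust,
                 trust_loop(rec$raw_score, rec$true_label, t),
                 tolerance = 1e-12)
    expect_true(all(rep$per_sample$Q >= 0 & rep$per_sample$Q <= 1))
    expect_equal(rep$n_positive, sum(rec$true_label == 1))
  }

  # perfectly confident and correct -> trust 1
  conf <- data.frame(id = c("a", "b"), raw_score = c(1 - 1e-15, 1 - 1e-15),
                     true_label = c(1, 1))
  expect_equal(positive_trust_score(conf, trust_params())$positive_trust, 1)
  # confidently wrong -> trust 0
  wrong <- data.frame(id = c("a", "b"), raw_score = c(1e-15, 1e-15),
                      true_label = c(1, 1))
  expect_equal(positive_trust_score(wrong, trust_params())$positive_trust, 0)
  expect_error(positive_trust_score(
    data.frame(id = "a", raw_score = 0.5, true_label = 0), trust_params()),
    "positive")
})

test_that("confident correctness earns more trust than marginal correctness", {
  # two models, identical accuracy on the same truth, different confidence
  y <- rep(c(1, 0), each = 20)
  confident <- ifelse(y == 1, 0.95, 0.05)
  marginal <- ifelse(y == 1, 0.52, 0.48)
  t <- 0.5
  rep_c <- positive_trust_score(
    data.frame(id = seq_along(y), raw_score = confident, true_label = y),
    trust_params(threshold = t))
  rep_m <- positive_trust_score(
    data.frame(id = seq_along(y), raw_score = marginal, true_label = y),
    trust_params(threshold = t))
  expect_gt(rep_c$positive_trust, rep_m$positive_trust)
})
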