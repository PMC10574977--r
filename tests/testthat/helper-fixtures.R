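# Shared fixtures and independent oracles. Expensive artifacts (generated
# datasets, trained models) are memoized per test run.

.fix <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# Small separable dataset (strong blob, light noise) with train/val/test
# records, used by training and explanation tests.
separable_dataset <- function() {
  memo("separable", function() {
    tr <- generate_synthetic_dataset(
      synthetic_spec(n_neg = 48, n_pos = 16, image_side = 32,
                     signal_amplitude = 0.6, noise_sd = 0.08, seed = 41),
      tempfile("septr"))
    te <- generate_synthetic_dataset(
      synthetic_spec(n_neg = 20, n_pos = 20, image_side = 32,
                     signal_amplitude = 0.6, noise_sd = 0.08,
                     split = "test", seed = 42),
      tempfile("septe"))
    image_dataset(rbind(tr$records, te$records), 32, validate = FALSE)
  })
}

# A model fine-tuned with the AUC margin loss on the separable data.
separable_fit <- function() {
  memo("separable_fit", function() {
    ds <- separable_dataset()
    sp <- balanced_validation_split(ds, 0.2, seed = 5)
    tv <- image_dataset(rbind(sp$train$records, sp$val$records),
                        ds$image_side, validate = FALSE)
    finetune(tv, encoder = tiny_cnn(seed = 7),
             config = finetune_config(loss = "auc_margin", epochs = 15,
                                      batch_size = 16, lr_primal = 0.05,
                                      seed = 11))
  })
}

# ---- independent oracles -------------------------------------------------

# NT-Xent by explicit enumeration of every anchor / partner / negative term.
ntxent_bruteforce <- function(E, tau) {
  n <- nrow(E)
  z <- E / sqrt(rowSums(E^2))
  s <- z %*% t(z)
  total <- 0
  for (i in seq_len(n)) {
    p <- if (i %% 2 == 1) i + 1 else i - 1
    den <- 0
    for (k in seq_len(n)) if (k != i) den <- den + exp(s[i, k] / tau)
    total <- total - log(exp(s[i, p] / tau) / den)
  }
  total / n
}

# Positive-class F1 of the rule score >= t.
f1_at <- function(scores, labels, t) {
  pred <- scores >= t
  tp <- sum(pred & labels == 1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + sum(pred & labels == 0) + sum(!pred & labels == 1))
}

# Exhaustive threshold search over the same candidate set contract.
best_f1_bruteforce <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(u[1] / 2, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2,
            (1 + u[length(u)]) / 2)
  max(vapply(cand, function(t) f1_at(scores, labels, t), numeric(1)))
}

# Pairwise Mann-Whitney AUC by double loop with half-credit ties.
auc_bruteforce <- function(scores, labels) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(ps) * length(ns))
}

# Scalar per-sample re-implementation of the trust pipeline.
trust_loop <- function(scores, labels, t, alpha = 1, beta = 1) {
  Q <- numeric(length(scores))
  for (i in seq_along(scores)) {
    y <- if (scores[i] >= t) 1L else 0L
    p <- if (scores[i] < t) 0.5 * scores[i] / t
    else 0.5 + 0.5 * (scores[i] - t) / (1 - t)
    C <- if (y == 1L) p else 1 - p
    Q[i] <- if (y == labels[i]) C^alpha else (1 - C)^beta
  }
  mean(Q[labels == 1])
}

random_mixed_batch <- function(n) {
  labels <- c(1, 0, rbinom(n - 2, 1, 0.4))
  list(scores = runif(n), labels = labels)
}

# Imbalanced-ablation harness: 20:1 training imbalance, balanced test
# split, equal epoch budget across arms. Memoized; also mirrored by
# scripts/acceptance.R.
ablation_trend_stats <- function(seeds = 1:5) {
  memo("trend", function() {
    auc_sl <- auc_full <- trust_sl <- trust_full <- numeric(0)
    for (seed in seeds) {
      tr <- generate_synthetic_dataset(
        synthetic_spec(300, 15, 32, signal_amplitude = 0.4, noise_sd = 0.15,
                       seed = 100 + seed), tempfile())
      te <- generate_synthetic_dataset(
        synthetic_spec(80, 80, 32, signal_amplitude = 0.4, noise_sd = 0.15,
                       split = "test", seed = 200 + seed), tempfile())
      ds <- image_dataset(rbind(tr$records, te$records), 32, validate = FALSE)
      for (arm in c("SL", "FULL")) {
        cfg <- run_config(
          ds, use_ssl = (arm == "FULL"),
          finetune_loss = if (arm == "FULL") "auc_margin" else "cross_entropy",
          ssl = ssl_config(epochs = 4, batch_pairs = 16),
          ft = finetune_config(epochs = 50, batch_size = 32, lr_primal = 0.15),
          seed = seed, log_level = "quiet")
        art <- suppressWarnings(run(cfg))
        if (arm == "SL") {
          auc_sl <- c(auc_sl, art$metrics$auc)
          trust_sl <- c(trust_sl, art$metrics$trust_pos)
        } else {
          auc_full <- c(auc_full, art$metrics$auc)
          trust_full <- c(trust_full, art$metrics$trust_pos)
        }
      }
    }
    list(auc_sl = auc_sl, auc_full = auc_full,
         trust_sl = trust_sl, trust_full = trust_full)
  })
}

# Toy-scale five-fold cross-validation of the supervised arm.
acceptance_cv <- function() {
  memo("acceptance_cv", function() {
    tr <- generate_synthetic_dataset(
      synthetic_spec(48, 16, 32, signal_amplitude = 0.6, noise_sd = 0.08,
                     seed = 71), tempfile())
    te <- generate_synthetic_dataset(
      synthetic_spec(12, 12, 32, signal_amplitude = 0.6, noise_sd = 0.08,
                     split = "test", seed = 72), tempfile())
    ds <- image_dataset(rbind(tr$records, te$records), 32, validate = FALSE)
    cfg <- run_config(ds, use_ssl = FALSE, finetune_loss = "cross_entropy",
                      ft = finetune_config(epochs = 2, batch_size = 16),
                      seed = 31, log_level = "quiet")
    cross_validate(cfg, k = 5)
  })
}
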