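#' Run configuration for the three-stage pipeline
#'
#' Bundles everything one end-to-end run needs: the dataset, the
#' (optional) self-supervised pre-training stage, the fine-tuning stage,
#' trust scoring, and model selection. The three supported arms are the
#' cumulative ablation configurations: `SL` (supervised fine-tuning only,
#' cross-entropy), `SL+SSL` (contrastive pre-training then cross-entropy
#' fine-tuning) and `SL+SSL+AUC` (contrastive pre-training then
#' AUC-margin fine-tuning).
#'
#' @param data either an `image_dataset`, a manifest path, or a
#'   [synthetic_spec()] (generated into a temporary directory).
#' @param use_ssl run the contrastive pre-training stage.
#' @param finetune_loss `"cross_entropy"` or `"auc_margin"`.
#' @param init_weights `"random"` or a path to a serialized encoder
#'   (standing in for large-scale supervised pre-training).
#' @param ssl an [ssl_config()].
#' @param ft a [finetune_config()] (its `loss` is overridden by
#'   `finetune_loss`).
#' @param policy an [augmentation_policy()] for the SSL stage.
#' @param trust a [trust_params()]; its threshold is refit on validation
#'   predictions at evaluation time.
#' @param val_fraction balanced validation fraction of the train split.
#' @param selection_criterion checkpoint used for reporting (best
#'   validation F1 by default, for consistency across arms).
#' @param seed master seed; stage seeds are derived from it.
#' @param out_dir optional artifact directory.
#' @param log_level `"info"` or `"quiet"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data, use_ssl = TRUE,
                       finetune_loss = c("auc_margin", "cross_entropy"),
                       init_weights = "random",
                       ssl = ssl_config(), ft = finetune_config(),
                       policy = augmentation_policy(),
                       trust = trust_params(),
                       val_fraction = 0.1,
                       selection_criterion = "best_val_f1",
                       seed = 1L, out_dir = NULL, log_level = "info") {
  finetune_loss <- match.arg(finetune_loss)
  if (!identical(init_weights, "random") && !file.exists(init_weights))
    stop("init_weights must be \"random\" or an existing weights file")
  structure(list(data = data, use_ssl = use_ssl, finetune_loss = finetune_loss,
                 init_weights = init_weights, ssl = ssl, ft = ft,
                 policy = policy, trust = trust, val_fraction = val_fraction,
                 selection_criterion = selection_criterion,
                 seed = as.integer(seed), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields mirror [run_config()] arguments; nested blocks `ssl`,
#' `ft`, `policy` and `trust` are passed to the respective constructors.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list(data = cfg$data %||% stop("config must name a data manifest"))
  for (f in c("use_ssl", "finetune_loss", "init_weights", "val_fraction",
              "selection_criterion", "seed", "out_dir", "log_level"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$ssl)) args$ssl <- do.call(ssl_config, cfg$ssl)
  if (!is.null(cfg$ft)) args$ft <- do.call(finetune_config, cfg$ft)
  if (!is.null(cfg$policy)) args$policy <- do.call(augmentation_policy, cfg$policy)
  if (!is.null(cfg$trust)) args$trust <- do.call(trust_params, cfg$trust)
  do.call(run_config, args)
}

run_log <- function(cfg, con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!identical(cfg$log_level, "quiet")) message(msg)
  if (!is.null(con)) writeLines(msg, con)
  invisible(NULL)
}

resolve_dataset <- function(data) {
  if (inherits(data, "image_dataset")) return(data)
  if (inherits(data, "synthetic_spec"))
    return(generate_synthetic_dataset(data, tempfile("synth")))
  if (is.character(data)) return(read_manifest(data))
  stop("unsupported data specification")
}

arm_name <- function(use_ssl, loss) {
  if (!use_ssl && loss == "cross_entropy") "SL"
  else if (use_ssl && loss == "cross_entropy") "SL+SSL"
  else if (use_ssl && loss == "auc_margin") "SL+SSL+AUC"
  else stop("inconsistent arm: use_ssl=", use_ssl, ", loss=", loss,
            " is not one of SL / SL+SSL / SL+SSL+AUC")
}

# Evaluate a selected snapshot on the test split: threshold calibrated on
# validation predictions, metrics at that threshold, exact AUC, and the
# question-answer trust report.
evaluate_snapshot <- function(snapshot, val_ds, test_ds, trust) {
  s_val <- predict(snapshot, val_ds)
  thr <- select_threshold(s_val, val_ds$records$label)
  s_te <- predict(snapshot, test_ds)
  y_te <- test_ds$records$label
  cm <- confusion_metrics(counts_at_threshold(s_te, y_te, as.numeric(thr)))
  rep <- positive_trust_score(
    data.frame(id = test_ds$records$id, raw_score = s_te, true_label = y_te),
    trust_params(trust$alpha, trust$beta, as.numeric(thr)))
  metrics <- c(cm, list(auc = roc_auc(s_te, y_te),
                        trust_pos = rep$positive_trust,
                        threshold = as.numeric(thr)))
  class(metrics) <- "metrics_report"
  list(metrics = metrics, trust = rep,
       predictions = data.frame(id = test_ds$records$id, raw_score = s_te,
                                true_label = y_te))
}

#' Execute one end-to-end pipeline run
#'
#' Resolves the dataset, carves a balanced validation split from its
#' train records, optionally runs contrastive pre-training on the
#' (unlabeled) training images, fine-tunes with the configured loss,
#' selects the reporting snapshot, and evaluates it on the test split —
#' performance metrics at the F1-calibrated threshold plus the
#' positive-class trust score. All artifacts (resolved config, history,
#' checkpoints, metrics JSON, trust report, log) are written when
#' `out_dir` is set.
#'
#' @param config a [run_config()].
#' @return an object of class `run_artifacts`: list with `arm`, `fit`,
#'   `selected`, `metrics`, `trust`, `predictions`, `ssl_loss_history`
#'   and `out_dir`.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  arm <- arm_name(config$use_ssl, config$finetune_loss)
  out_dir <- config$out_dir
  con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    con <- file(file.path(out_dir, "run.log"), open = "wt")
    on.exit(close(con))
  }
  run_log(config, con, "arm=", arm, " seed=", config$seed)

  ds <- resolve_dataset(config$data)
  has_test <- any(ds$records$split == "test")
  sp <- balanced_validation_split(ds, config$val_fraction,
                                  seed = derive_seed(config$seed, "split"))
  trainval <- image_dataset(rbind(sp$train$records, sp$val$records),
                            ds$image_side, validate = FALSE)
  run_log(config, con, "train=", nrow(sp$train$records),
          " val=", nrow(sp$val$records))

  encoder <- if (identical(config$init_weights, "random"))
    tiny_cnn(seed = derive_seed(config$seed, "init"))
  else readRDS(config$init_weights)

  ssl_hist <- NULL
  if (config$use_ssl) {
    sslc <- config$ssl; sslc$seed <- derive_seed(config$seed, "ssl")
    pt <- pretrain_encoder(encoder, sp$train, config$policy, sslc,
                           checkpoint_path = if (!is.null(out_dir))
                             file.path(out_dir, "ssl_encoder.rds"))
    encoder <- pt$encoder
    ssl_hist <- pt$loss_history
    run_log(config, con, "ssl done: final loss ",
            formatC(ssl_hist[length(ssl_hist)], digits = 4, format = "f"))
  }

  ftc <- config$ft
  ftc$loss <- config$finetune_loss
  ftc$seed <- derive_seed(config$seed, "finetune")
  fit <- finetune(trainval, encoder = encoder, config = ftc,
                  checkpoint_dir = if (!is.null(out_dir))
                    file.path(out_dir, "checkpoints"))
  run_log(config, con, "finetune done: final val auc ",
          formatC(fit$history$val_auc[nrow(fit$history)], digits = 3,
                  format = "f"))

  selected <- select_model(fit, config$selection_criterion)
  test_ds <- if (has_test) subset_dataset(ds, ds$records$split == "test")
  else sp$val
  if (!has_test)
    run_log(config, con, "no test split; reporting on the validation split")
  ev <- evaluate_snapshot(selected, sp$val, test_ds, config$trust)
  run_log(config, con, "test auc=", formatC(ev$metrics$auc, digits = 3,
                                            format = "f"),
          " trust=", formatC(ev$metrics$trust_pos, digits = 3, format = "f"))

  art <- structure(
    list(arm = arm, fit = fit, selected = selected, metrics = ev$metrics,
         trust = ev$trust, predictions = ev$predictions,
         ssl_loss_history = ssl_hist, out_dir = out_dir),
    class = "run_artifacts")
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(ev$metrics), file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_trust_report(ev$trust, out_dir)
    utils::write.csv(ev$predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    resolved <- config
    resolved$data <- if (is.character(config$data)) config$data else "inline"
    jsonlite::write_json(rapply(unclass(resolved), unclass, how = "replace"),
                         file.path(out_dir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(ssl_hist))
      utils::write.csv(data.frame(epoch = seq_along(ssl_hist),
                                  ssl_loss = ssl_hist),
                       file.path(out_dir, "ssl_history.csv"), row.names = FALSE)
  }
  art
}

#' @export
print.run_artifacts <- function(x, ...) {
  cat("<run_artifacts> arm ", x$arm, "\n", sep = "")
  cat(sprintf("  test: auc %.3f | f1 %.3f | acc %.3f | trust %.3f\n",
              x$metrics$auc, x$metrics$f1_pos, x$metrics$accuracy,
              x$metrics$trust_pos))
  invisible(x)
}

#' Cumulative ablation over the three pipeline arms
#'
#' Runs `SL`, `SL+SSL` and `SL+SSL+AUC` on the same dataset and seed and
#' tabulates per-arm positive/negative precision and sensitivity, AUC and
#' the positive-class trust score. If an arm fails, the completed arms
#' are preserved in the error's `partial` attribute.
#'
#' @param config a [run_config()]; its `use_ssl`/`finetune_loss` are
#'   overridden per arm.
#' @return data frame with rows `SL`, `SL+SSL`, `SL+SSL+AUC` and attribute
#'   `"runs"` holding the full `run_artifacts`.
#' @export
ablation <- function(config) {
  arms <- list(SL = c(FALSE, "cross_entropy"),
               `SL+SSL` = c(TRUE, "cross_entropy"),
               `SL+SSL+AUC` = c(TRUE, "auc_margin"))
  ds <- resolve_dataset(config$data)   # shared data across arms
  runs <- list()
  rows <- list()
  for (nm in names(arms)) {
    cfg <- config
    cfg$data <- ds
    cfg$use_ssl <- as.logical(arms[[nm]][1])
    cfg$finetune_loss <- arms[[nm]][2]
    if (!is.null(config$out_dir)) cfg$out_dir <- file.path(config$out_dir, nm)
    art <- tryCatch(run(cfg), error = function(e) {
      err <- simpleError(paste0("arm ", nm, " failed: ", conditionMessage(e)))
      attr(err, "partial") <- runs
      stop(err)
    })
    runs[[nm]] <- art
    m <- art$metrics
    rows[[nm]] <- data.frame(arm = nm, precision_pos = m$precision_pos,
                             precision_neg = m$precision_neg,
                             sensitivity_pos = m$sensitivity_pos,
                             sensitivity_neg = m$sensitivity_neg,
                             auc = m$auc, trust = m$trust_pos)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(config$out_dir))
    utils::write.csv(tab, file.path(config$out_dir, "ablation.csv"),
                     row.names = FALSE)
  structure(tab, runs = runs)
}

#' Stratified k-fold cross-validation of the fine-tuning stage
#'
#' Splits the training records into k stratified folds; each fold's model
#' is fine-tuned on the remaining folds (fold members serve as the
#' validation split), then evaluated on the fixed test split. The summary
#' reports, per metric, the fold mean plus-minus half the range
#' (max minus min, halved), printed as `value±percent` — the dispersion
#' convention is recorded in the output metadata.
#'
#' @param config a [run_config()].
#' @param k number of folds.
#' @return list of class `cv_result`: `folds` (per-fold metrics data
#'   frame), `summary` (mean and half-range per metric), `formatted`
#'   (`value±percent` strings) and `dispersion` (`"half_range"`).
#' @export
cross_validate <- function(config, k = 5L) {
  ds <- resolve_dataset(config$data)
  train_ds <- subset_dataset(ds, ds$records$split == "train")
  has_test <- any(ds$records$split == "test")
  if (!has_test) stop("cross-validation needs a fixed test split to report on")
  test_ds <- subset_dataset(ds, ds$records$split == "test")
  folds <- kfold_splits(train_ds, k = k, seed = derive_seed(config$seed, "cv"))
  rows <- list()
  for (f in seq_len(k)) {
    fold_ds <- image_dataset(rbind(folds[[f]]$train$records,
                                   folds[[f]]$val$records),
                             ds$image_side, validate = FALSE)
    encoder <- if (identical(config$init_weights, "random"))
      tiny_cnn(seed = derive_seed(config$seed, "init"))
    else readRDS(config$init_weights)
    if (config$use_ssl) {
      sslc <- config$ssl; sslc$seed <- derive_seed(config$seed, paste0("ssl", f))
      encoder <- pretrain_encoder(encoder, folds[[f]]$train, config$policy,
                                  sslc)$encoder
    }
    ftc <- config$ft
    ftc$loss <- config$finetune_loss
    ftc$seed <- derive_seed(config$seed, paste0("ft", f))
    fit <- finetune(fold_ds, encoder = encoder, config = ftc)
    sel <- select_model(fit, config$selection_criterion)
    ev <- evaluate_snapshot(sel, folds[[f]]$val, test_ds, config$trust)
    m <- ev$metrics
    rows[[f]] <- data.frame(fold = f, precision_pos = m$precision_pos,
                            precision_neg = m$precision_neg,
                            sensitivity_pos = m$sensitivity_pos,
                            sensitivity_neg = m$sensitivity_neg,
                            auc = m$auc, trust = m$trust_pos)
  }
  per_fold <- do.call(rbind, rows)
  met <- setdiff(names(per_fold), "fold")
  mean_v <- vapply(per_fold[met], mean, numeric(1))
  half_range <- vapply(per_fold[met], function(v) (max(v) - min(v)) / 2,
                       numeric(1))
  formatted <- sprintf("%.3f±%.1f%%", mean_v, 100 * half_range)
  names(formatted) <- met
  res <- structure(list(folds = per_fold,
                        summary = data.frame(metric = met, mean = mean_v,
                                             half_range = half_range,
                                             row.names = NULL),
                        formatted = formatted, dispersion = "half_range",
                        k = k),
                   class = "cv_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_fold, file.path(config$out_dir, "cv_folds.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = res$summary, formatted = formatted,
                              dispersion = "half_range", k = k),
                         file.path(config$out_dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$k, "-fold cross-validation (mean ± half-range)\n",
      sep = "")
  for (m in names(x$formatted))
    cat(sprintf("  %-16s %s\n", m, x$formatted[[m]]))
  invisible(x)
}
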