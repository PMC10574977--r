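#' Fine-tuning configuration
#'
#' @param loss `"auc_margin"` (min-max margin surrogate for the ROC AUC,
#'   suited to class imbalance) or `"cross_entropy"` (ablation baseline).
#' @param lr_primal learning rate for model weights and the primal
#'   auxiliaries of the AUC surrogate.
#' @param lr_dual learning rate for the dual variable (defaults to
#'   `lr_primal`).
#' @param margin margin `m` of the AUC surrogate.
#' @param epochs training epochs.
#' @param batch_size samples per batch.
#' @param seed RNG seed (batching, head initialization).
#' @return an object of class `finetune_config`.
#' @export
finetune_config <- function(loss = c("auc_margin", "cross_entropy"),
                            lr_primal = 0.1, lr_dual = NULL, margin = 1,
                            epochs = 20L, batch_size = 32L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(lr_primal > 0, margin > 0, epochs >= 1, batch_size >= 2)
  structure(list(loss = loss, lr_primal = lr_primal,
                 lr_dual = lr_dual %||% lr_primal, margin = margin,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "finetune_config")
}

# Stratified batches: every batch carries >= 1 positive and >= 1 negative
# (required by the AUC surrogate). Positives are dealt round-robin across
# batches after shuffling both classes.
stratified_batches <- function(labels, batch_size) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  if (!length(pos) || !length(neg))
    stop("stratified batching needs both classes in the training split")
  n <- length(labels)
  nb <- max(1L, floor(n / batch_size))
  if (nb > min(length(pos), length(neg)))
    nb <- min(length(pos), length(neg))
  pos <- sample(pos); neg <- sample(neg)
  bpos <- split(pos, rep_len(seq_len(nb), length(pos)))
  bneg <- split(neg, rep_len(seq_len(nb), length(neg)))
  lapply(seq_len(nb), function(i) sample(c(bpos[[i]], bneg[[i]])))
}

plain_batches <- function(n, batch_size) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batch_size))
}

model_scores <- function(encoder, head, x, keep_cache = FALSE) {
  fw <- encoder_forward(encoder, x, keep_cache = keep_cache)
  logit <- as.vector(fw$features %*% head$w) + head$b
  list(scores = sigmoid(logit), features = fw$features, cache = fw$cache)
}

# forward in chunks to bound memory on large evaluation sets
scores_in_chunks <- function(encoder, head, x, chunk = 256L) {
  n <- dim(x)[4]
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    out[i0:i1] <- model_scores(encoder, head,
                               x[, , , i0:i1, drop = FALSE])$scores
  }
  out
}

eval_split <- function(encoder, head, x, labels, loss, state) {
  s <- scores_in_chunks(encoder, head, x)
  cm <- confusion_metrics(counts_at_threshold(s, labels, 0.5))
  val_loss <- if (loss == "auc_margin")
    auc_margin_objective(s, labels, state)
  else cross_entropy(pmin(pmax(s, 1e-12), 1 - 1e-12), labels)
  list(acc = cm$accuracy, f1 = if (is.na(cm$f1_pos)) 0 else cm$f1_pos,
       auc = roc_auc(s, labels), loss = val_loss, scores = s)
}

#' Fine-tune an encoder into a calibrated binary classifier
#'
#' Trains the encoder plus a one-output sigmoid head end-to-end on a
#' dataset's `train` split, evaluating on its `val` split each epoch.
#' With `loss = "auc_margin"` the min-max margin surrogate for the ROC
#' AUC is optimized by primal-dual stochastic gradients over stratified
#' batches (each holding both classes), with the dual variable projected
#' to `[0, Inf)` after every step; with `loss = "cross_entropy"` standard
#' SGD on plain shuffled batches is used. Five model snapshots are kept:
#' best validation accuracy, best validation AUC, best validation F1,
#' lowest validation loss, and the last epoch; ties go to the earliest
#' epoch.
#'
#' @param dataset an `image_dataset` whose `train` and `val` splits each
#'   contain both classes.
#' @param encoder starting encoder, e.g. a freshly initialized or
#'   pre-trained [tiny_cnn()]; the classifier head is always newly
#'   initialized.
#' @param config a [finetune_config()].
#' @param checkpoint_dir optional directory; when given, each snapshot is
#'   also serialized there with a sidecar JSON.
#' @return an object of class `trustauc_fit` with components `encoder`,
#'   `head`, `config`, `history` (per-epoch data frame), `checkpoints`
#'   (five snapshots), `auc_state` and `alpha_trace`.
#' @export
finetune <- function(dataset, encoder = NULL, config = finetune_config(),
                     checkpoint_dir = NULL) {
  rec <- dataset$records
  for (sp in c("train", "val")) {
    lab <- rec$label[rec$split == sp]
    if (!any(lab == 1) || !any(lab == 0))
      stop("split '", sp, "' must contain both classes")
  }
  tr <- subset_dataset(dataset, rec$split == "train")
  va <- subset_dataset(dataset, rec$split == "val")
  x_tr <- load_images(tr); y_tr <- tr$records$label
  x_va <- load_images(va); y_va <- va$records$label
  if (is.null(encoder)) encoder <- tiny_cnn(seed = config$seed)

  state <- auc_margin_state(a = 0.5, b = 0.5, alpha = 0, margin = config$margin)
  alpha_trace <- numeric(0)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_acc = numeric(0), val_auc = numeric(0),
                     val_f1 = numeric(0), val_loss = numeric(0))
  crit <- c("best_val_accuracy", "best_val_auc", "best_val_f1",
            "lowest_val_loss", "last_epoch")
  best <- list(best_val_accuracy = -Inf, best_val_auc = -Inf,
               best_val_f1 = -Inf, lowest_val_loss = Inf)
  checkpoints <- stats::setNames(vector("list", 5L), crit)
  snap <- function(epoch, metrics)
    list(encoder = encoder, head = head, state = state,
         epoch = epoch, val_metrics = metrics)

  with_seed(config$seed, {
    head <- list(w = stats::rnorm(encoder$feature_dim,
                                  sd = 1 / sqrt(encoder$feature_dim)),
                 b = 0)
    for (ep in seq_len(config$epochs)) {
      batches <- if (config$loss == "auc_margin")
        stratified_batches(y_tr, config$batch_size)
      else plain_batches(length(y_tr), config$batch_size)
      ep_loss <- 0; ep_n <- 0L
      for (bt in batches) {
        xb <- x_tr[, , , bt, drop = FALSE]
        yb <- y_tr[bt]
        fw <- model_scores(encoder, head, xb, keep_cache = TRUE)
        s <- fw$scores
        if (config$loss == "auc_margin") {
          g <- auc_margin_grads(s, yb, state)
          batch_loss <- auc_margin_objective(s, yb, state)
          ds <- g$dscores
        } else {
          ce <- cross_entropy(pmin(pmax(s, 1e-12), 1 - 1e-12), yb, grad = TRUE)
          batch_loss <- ce$loss
          ds <- ce$dscores
        }
        dlogit <- ds * s * (1 - s)             # through the sigmoid
        dw <- as.vector(crossprod(fw$features, dlogit))
        db <- sum(dlogit)
        dfeat <- outer(dlogit, head$w)
        enc_grads <- encoder_backward(encoder, fw$cache, dfeat)
        if (!all(vapply(enc_grads, function(g2) all(is.finite(g2)), logical(1))))
          stop("non-finite encoder gradient at epoch ", ep)
        encoder$params <- sgd_step(encoder$params, enc_grads, config$lr_primal)
        head$w <- head$w - config$lr_primal * dw
        head$b <- head$b - config$lr_primal * db
        if (config$loss == "auc_margin") {
          state <- pdsg_update(state, g, config$lr_primal, config$lr_dual)
          alpha_trace <- c(alpha_trace, state$alpha)
        }
        ep_loss <- ep_loss + batch_loss * length(bt)
        ep_n <- ep_n + length(bt)
      }
      ev <- eval_split(encoder, head, x_va, y_va, config$loss, state)
      hist[ep, ] <- list(ep, ep_loss / ep_n, ev$acc, ev$auc, ev$f1, ev$loss)
      metrics <- list(val_acc = ev$acc, val_auc = ev$auc,
                      val_f1 = ev$f1, val_loss = ev$loss)
      if (ev$acc > best$best_val_accuracy) {
        best$best_val_accuracy <- ev$acc
        checkpoints$best_val_accuracy <- snap(ep, metrics)
      }
      if (ev$auc > best$best_val_auc) {
        best$best_val_auc <- ev$auc
        checkpoints$best_val_auc <- snap(ep, metrics)
      }
      if (ev$f1 > best$best_val_f1) {
        best$best_val_f1 <- ev$f1
        checkpoints$best_val_f1 <- snap(ep, metrics)
      }
      if (ev$loss < best$lowest_val_loss) {
        best$lowest_val_loss <- ev$loss
        checkpoints$lowest_val_loss <- snap(ep, metrics)
      }
      if (ep == config$epochs) checkpoints$last_epoch <- snap(ep, metrics)
    }
    fit <- structure(
      list(encoder = encoder, head = head, config = config, history = hist,
           checkpoints = checkpoints, auc_state = state,
           alpha_trace = alpha_trace, image_side = dataset$image_side),
      class = "trustauc_fit")
  })
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
    for (cr in crit) {
      path <- file.path(checkpoint_dir, paste0(cr, ".rds"))
      saveRDS(fit$checkpoints[[cr]], path)
      jsonlite::write_json(
        c(list(criterion = cr, epoch = fit$checkpoints[[cr]]$epoch),
          fit$checkpoints[[cr]]$val_metrics),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
      fit$checkpoints[[cr]]$path <- path
    }
    utils::write.csv(fit$history, file.path(checkpoint_dir, "history.csv"),
                     row.names = FALSE)
  }
  fit
}

#' Pick a saved model snapshot by selection criterion
#'
#' When comparing arms or architectures the best-validation-F1 snapshot
#' is used throughout for consistency; the other four criteria remain
#' available.
#'
#' @param fit a `trustauc_fit` (or its `checkpoints` list).
#' @param criterion one of `"best_val_accuracy"`, `"best_val_auc"`,
#'   `"best_val_f1"`, `"lowest_val_loss"`, `"last_epoch"`.
#' @return the stored snapshot (`encoder`, `head`, `state`, `epoch`,
#'   `val_metrics`, and `path` if serialized).
#' @export
select_model <- function(fit, criterion = "best_val_f1") {
  cps <- if (inherits(fit, "trustauc_fit")) fit$checkpoints else fit
  if (!criterion %in% names(cps))
    stop("unknown selection criterion: ", criterion)
  structure(cps[[criterion]], class = "trustauc_snapshot")
}

#' @rdname predict.trustauc_fit
#' @export
predict.trustauc_snapshot <- function(object, newdata,
                                      type = c("score", "label"),
                                      threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "image_dataset")) load_images(newdata) else newdata
  s <- scores_in_chunks(object$encoder, object$head, x)
  if (type == "score") s else as.integer(s >= threshold)
}

#' @export
print.trustauc_fit <- function(x, ...) {
  h <- x$history
  cat("<trustauc_fit> loss=", x$config$loss, ", ", nrow(h), " epochs\n", sep = "")
  cat(sprintf("  final val: acc %.3f | auc %.3f | f1 %.3f | loss %.4f\n",
              h$val_acc[nrow(h)], h$val_auc[nrow(h)],
              h$val_f1[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.trustauc_fit <- function(object, ...) {
  h <- object$history
  cat("Fine-tuned binary image classifier (", object$config$loss, " loss)\n",
      sep = "")
  cat("Epochs:", nrow(h), " batch size:", object$config$batch_size, "\n")
  for (cr in names(object$checkpoints)) {
    cp <- object$checkpoints[[cr]]
    cat(sprintf("  %-18s epoch %3d  val_f1 %.3f  val_auc %.3f\n",
                cr, cp$epoch, cp$val_metrics$val_f1, cp$val_metrics$val_auc))
  }
  if (object$config$loss == "auc_margin")
    cat(sprintf("AUC surrogate state: a=%.3f b=%.3f alpha=%.3f (margin %.2f)\n",
                object$auc_state$a, object$auc_state$b,
                object$auc_state$alpha, object$auc_state$margin))
  invisible(object)
}

#' Predict scores or labels from a fitted classifier
#'
#' @param object a `trustauc_fit` or a snapshot from [select_model()].
#' @param newdata an `image_dataset` or an image array `(H, W, 1, n)`.
#' @param type `"score"` for sigmoid scores, `"label"` for thresholded
#'   0/1 answers.
#' @param threshold decision threshold for `type = "label"`.
#' @param ... unused.
#' @return numeric vector of scores or integer labels.
#' @export
predict.trustauc_fit <- function(object, newdata, type = c("score", "label"),
                                 threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "image_dataset")) load_images(newdata) else newdata
  s <- scores_in_chunks(object$encoder, object$head, x)
  if (type == "score") s else as.integer(s >= threshold)
}

#' @export
coef.trustauc_fit <- function(object, ...)
  c(object$head$w, bias = object$head$b)

#' Plot training history
#'
#' Draws per-epoch training loss and validation AUC/F1 curves.
#'
#' @param x a `trustauc_fit`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.trustauc_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = x$config$loss, ...)
  graphics::matplot(h$epoch, cbind(h$val_auc, h$val_f1), type = "l", lty = 1,
                    col = c("black", "grey50"), xlab = "epoch",
                    ylab = "validation metric", ...)
  graphics::legend("bottomright", c("AUC", "F1"), lty = 1,
                   col = c("black", "grey50"), bty = "n")
  invisible(x)
}
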