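#' Normalized-temperature contrastive (NT-Xent) loss
#'
#' Computes the contrastive loss over a batch of `2N` embeddings laid out
#' so that rows `2i - 1` and `2i` are the two views of image `i`. Each row
#' is L2-normalized, similarities are cosine, and the loss is the mean
#' over all `2N` anchors of
#' `-log( exp(sim(anchor, partner)/tau) / sum_{k != anchor} exp(sim(anchor, k)/tau) )`.
#' With all embeddings identical the loss equals `log(2N - 1)` for any
#' `N`, a closed form used in the test suite.
#'
#' @param embeddings numeric `2N x d` matrix, `N >= 2`; no all-zero rows.
#' @param tau temperature, `> 0`.
#' @param grad also return the gradient with respect to the (unnormalized)
#'   embeddings.
#' @return the scalar loss, or (with `grad = TRUE`) a list
#'   `list(loss, grad)`.
#' @export
nt_xent <- function(embeddings, tau = 0.5, grad = FALSE) {
  stopifnot(is.matrix(embeddings), tau > 0)
  n2 <- nrow(embeddings)
  if (n2 %% 2L != 0L || n2 < 4L)
    stop("embeddings must hold N >= 2 view pairs (an even number of rows >= 4)")
  nrm <- sqrt(rowSums(embeddings^2))
  if (any(nrm == 0)) stop("all-zero embedding rows cannot be normalized")
  z <- embeddings / nrm
  s <- tcrossprod(z) / tau                 # cosine similarities / tau
  diag(s) <- -Inf                          # an anchor never matches itself
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  m <- apply(s, 1, max)
  expS <- exp(s - m)                       # row-wise stabilized softmax
  denom <- rowSums(expS)
  logprob <- (s - m) - log(denom)
  loss <- -mean(logprob[cbind(seq_len(n2), partner)])
  if (!grad) return(loss)
  # d loss / d s[i, k], counting only anchor i's term
  G <- expS / denom
  G[cbind(seq_len(n2), partner)] <- G[cbind(seq_len(n2), partner)] - 1
  G <- G / n2
  G[!is.finite(s)] <- 0
  dz <- ((G + t(G)) %*% z) / tau
  # through the L2 normalization: dz -> du with u the raw embeddings
  du <- (dz - z * rowSums(dz * z)) / nrm
  list(loss = loss, grad = du)
}

#' Configuration for contrastive self-supervised pre-training
#'
#' @param temperature softmax temperature of the contrastive loss.
#' @param batch_pairs number of images per batch (each contributes two
#'   views), `>= 2`.
#' @param epochs training epochs.
#' @param learning_rate constant SGD learning rate.
#' @param projection_dim output width of the 2-layer projection head that
#'   is attached for training and stripped from the returned encoder.
#' @param seed RNG seed governing augmentation sampling, batch order and
#'   head initialization.
#' @return an object of class `ssl_config`.
#' @export
ssl_config <- function(temperature = 0.5, batch_pairs = 16L, epochs = 10L,
                       learning_rate = 0.1, projection_dim = 128L, seed = 1L) {
  stopifnot(temperature > 0, batch_pairs >= 2, epochs >= 1, learning_rate > 0,
            projection_dim >= 1)
  structure(list(temperature = temperature, batch_pairs = as.integer(batch_pairs),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 projection_dim = as.integer(projection_dim),
                 seed = as.integer(seed)),
            class = "ssl_config")
}

init_projection_head <- function(feature_dim, projection_dim) {
  h <- feature_dim
  list(P1 = matrix(stats::rnorm(feature_dim * h, sd = sqrt(2 / feature_dim)),
                   feature_dim, h),
       pb1 = numeric(h),
       P2 = matrix(stats::rnorm(h * projection_dim, sd = sqrt(2 / h)),
                   h, projection_dim),
       pb2 = numeric(projection_dim))
}

# The projection head batch-centers the incoming features before the
# 2-layer MLP. Encoder features are non-negative (post-ReLU averages), so
# uncentered embeddings share a large common component that compresses all
# cosine similarities toward 1 and stalls the contrastive gradient;
# centering plays the role of the normalization layer in canonical
# contrastive projection heads.
projection_forward <- function(head, f) {
  fc <- sweep(f, 2, colMeans(f))
  a <- fc %*% head$P1 + rep(head$pb1, each = nrow(f))
  hrelu <- pmax(a, 0)
  list(z = hrelu %*% head$P2 + rep(head$pb2, each = nrow(f)),
       hrelu = hrelu, mask = a > 0, fc = fc)
}

projection_backward <- function(head, cache, f, dz) {
  dP2 <- crossprod(cache$hrelu, dz)
  dpb2 <- colSums(dz)
  dh <- (dz %*% t(head$P2)) * cache$mask
  dP1 <- crossprod(cache$fc, dh)
  dpb1 <- colSums(dh)
  dfc <- dh %*% t(head$P1)
  df <- sweep(dfc, 2, colMeans(dfc))   # through the batch centering
  list(grads = list(P1 = dP1, pb1 = dpb1, P2 = dP2, pb2 = dpb2), df = df)
}

#' Contrastive self-supervised pre-training of an encoder
#'
#' Trains the encoder on unlabeled images by pulling together the
#' embeddings of two augmented views of each image and pushing apart all
#' other batch members (NT-Xent objective), through a temporary 2-layer
#' projection head. Labels are never read: only record paths are touched.
#'
#' @param encoder a [tiny_cnn()] (or compatible) encoder; trained in place
#'   functionally and returned.
#' @param dataset an `image_dataset`; only image files are used.
#' @param policy an [augmentation_policy()].
#' @param config an [ssl_config()].
#' @param checkpoint_path optional path; when given, the trained encoder
#'   (projection head stripped) is serialized there with a sidecar JSON.
#' @return list with `encoder` (trained, no projection head),
#'   `loss_history` (per-epoch mean loss) and `checkpoint_path`.
#' @export
pretrain_encoder <- function(encoder, dataset, policy = augmentation_policy(),
                             config = ssl_config(), checkpoint_path = NULL) {
  n <- nrow(dataset$records)
  if (n == 0L) stop("cannot pre-train on an empty dataset")
  if (config$batch_pairs > n)
    stop("batch_pairs (", config$batch_pairs, ") exceeds dataset size (", n, ")")
  imgs <- load_images(dataset)
  side <- dataset$image_side
  loss_history <- numeric(config$epochs)
  with_seed(config$seed, {
    head <- init_projection_head(encoder$feature_dim, config$projection_dim)
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_pairs))
      # drop a trailing runt that cannot form a valid contrastive batch
      batches <- Filter(function(b) length(b) >= 2, batches)
      ep_loss <- 0; ep_n <- 0L
      for (b in batches) {
        nb <- length(b)
        x <- array(0, c(side, side, 1L, 2L * nb))
        for (i in seq_len(nb)) {
          v <- make_views(imgs[, , 1L, b[i]], policy)
          x[, , 1L, 2L * i - 1L] <- v$view_a
          x[, , 1L, 2L * i] <- v$view_b
        }
        fw <- encoder_forward(encoder, x, keep_cache = TRUE)
        pf <- projection_forward(head, fw$features)
        nx <- nt_xent(pf$z, config$temperature, grad = TRUE)
        pb <- projection_backward(head, pf, fw$features, nx$grad)
        enc_grads <- encoder_backward(encoder, fw$cache, pb$df)
        encoder$params <- sgd_step(encoder$params, enc_grads, config$learning_rate)
        head <- sgd_step(head, pb$grads, config$learning_rate)
        ep_loss <- ep_loss + nx$loss * nb
        ep_n <- ep_n + nb
      }
      loss_history[ep] <- ep_loss / ep_n
    }
  })
  if (any(!is.finite(loss_history)))
    stop("non-finite contrastive loss encountered during pre-training")
  if (!is.null(checkpoint_path)) {
    saveRDS(encoder, checkpoint_path)
    meta <- list(epochs = config$epochs, temperature = config$temperature,
                 batch_pairs = config$batch_pairs,
                 projection_dim = config$projection_dim,
                 final_loss = loss_history[config$epochs])
    jsonlite::write_json(meta, paste0(checkpoint_path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(encoder = encoder, loss_history = loss_history,
       checkpoint_path = checkpoint_path)
}
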