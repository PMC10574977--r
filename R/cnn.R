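# Minimal convolutional encoder with explicit backpropagation.
#
# Layout conventions, used consistently throughout:
#   * image batches are arrays (H, W, C, B);
#   * 3x3 convolutions use zero padding 1 and stride 1 (cross-correlation);
#   * kernels are arrays (3, 3, C_in, C_out) so matrix(W, 9*C_in, C_out)
#     matches the im2col column order (kernel row fastest, then kernel
#     column, then input channel).
# Convolutions are evaluated as one GEMM per layer over an im2col gather;
# the input gradient is itself a convolution with the 180-degree-rotated,
# channel-transposed kernel, so no scatter-add is ever needed.

.idx_cache <- new.env(parent = emptyenv())

# Linear gather indices turning a zero-padded (H+2, W+2, C, B) array into
# the (H*W*B) x (9*C) im2col matrix. Cached per shape.
im2col_indices <- function(H, W, C, B) {
  key <- paste(H, W, C, B, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  i <- rep(seq_len(H), times = W)           # output row, fastest
  j <- rep(seq_len(W), each = H)            # output column
  M <- matrix(0L, H * W, 9L * C)
  col <- 0L
  for (ci in seq_len(C)) for (dy in 0:2) for (dx in 0:2) {
    col <- col + 1L
    M[, col] <- (i + dx) + Hp * ((j + dy - 1L) + Wp * (ci - 1L))
  }
  off <- (seq_len(B) - 1L) * Hp * Wp * C
  idx <- M[rep(seq_len(H * W), B), , drop = FALSE] + rep(off, each = H * W)
  .idx_cache[[key]] <- idx
  idx
}

pad1 <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3], d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), , ] <- x
  out
}

# 3x3 same convolution; returns the output and (optionally) the im2col
# matrix needed for the weight gradient.
conv3x3 <- function(x, W, b, keep_cache = FALSE) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; B <- d[4]
  Cout <- dim(W)[4]
  idx <- im2col_indices(H, Wd, C, B)
  Xcol <- matrix(pad1(x)[as.vector(idx)], nrow = H * Wd * B)
  out <- Xcol %*% matrix(W, 9L * C, Cout)
  out <- out + rep(b, each = H * Wd * B)
  out <- aperm(array(out, c(H, Wd, B, Cout)), c(1, 2, 4, 3))
  if (keep_cache) list(out = out, Xcol = Xcol) else list(out = out)
}

conv3x3_backward <- function(dout, Xcol, W, in_channels) {
  d <- dim(dout); H <- d[1]; Wd <- d[2]; Cout <- d[3]; B <- d[4]
  doutM <- matrix(aperm(dout, c(1, 2, 4, 3)), H * Wd * B, Cout)
  dW <- array(crossprod(Xcol, doutM), dim(W))
  db <- colSums(doutM)
  # input gradient = convolution of dout with the rotated, transposed kernel
  Wt <- aperm(W[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  dx <- conv3x3(dout, Wt, numeric(in_channels))$out
  list(dx = dx, dW = dW, db = db)
}

meanpool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
     x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
}

meanpool2_backward <- function(dout, in_dim) {
  dx <- array(0, in_dim)
  d <- dim(dout)
  o1 <- seq(1L, in_dim[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, in_dim[2], 2L); e2 <- o2 + 1L
  g <- dout / 4
  dx[o1, o2, , ] <- g; dx[e1, o2, , ] <- g
  dx[o1, e2, , ] <- g; dx[e1, e2, , ] <- g
  dx
}

global_avg_pool <- function(x) {
  d <- dim(x)
  t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
}

global_avg_pool_backward <- function(dfeat, in_dim) {
  array(rep(as.vector(t(dfeat)) / (in_dim[1] * in_dim[2]),
            each = in_dim[1] * in_dim[2]), in_dim)
}

#' Small convolutional encoder
#'
#' A compact two-convolution encoder (3x3 conv, ReLU, 2x2 mean-pool, twice,
#' then global average pooling) mapping a batch of square grayscale images
#' to feature vectors. It is the default backbone for desk-scale runs; any
#' object with [encoder_forward()] / [encoder_backward()] methods can stand
#' in for it, so deeper backbones plug in without touching the training
#' code.
#'
#' @param channels widths of the two convolution layers.
#' @param in_channels input image channels (1 for grayscale).
#' @param seed RNG seed for He-normal weight initialization.
#' @return an object of class `tiny_cnn`; `$feature_dim` gives the encoder
#'   output width.
#' @export
tiny_cnn <- function(channels = c(8L, 16L), in_channels = 1L, seed = 1L) {
  he <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  params <- with_seed(seed, list(
    W1 = array(he(9 * in_channels, 9 * in_channels * channels[1]),
               c(3, 3, in_channels, channels[1])),
    b1 = numeric(channels[1]),
    W2 = array(he(9 * channels[1], 9 * channels[1] * channels[2]),
               c(3, 3, channels[1], channels[2])),
    b2 = numeric(channels[2])))
  structure(list(params = params, channels = channels,
                 in_channels = in_channels, feature_dim = channels[2]),
            class = "tiny_cnn")
}

#' Encoder forward / backward pass
#'
#' `encoder_forward()` maps an image batch `(H, W, C, B)` to a `B x d`
#' feature matrix (the penultimate representation, before any task head);
#' with `keep_cache = TRUE` it also returns the activations needed by
#' `encoder_backward()`, which turns a feature-gradient matrix into
#' parameter gradients.
#'
#' @param encoder an encoder object such as [tiny_cnn()].
#' @param x image batch, array `(H, W, C, B)` with side divisible by 4.
#' @param keep_cache retain intermediate activations for the backward pass.
#' @param ... method extensions.
#' @return `encoder_forward`: list with `features` (`B x d`) and, when
#'   requested, `cache`; `encoder_backward`: list of parameter gradients
#'   matching `encoder$params`.
#' @export
encoder_forward <- function(encoder, x, keep_cache = FALSE, ...)
  UseMethod("encoder_forward")

#' @export
encoder_forward.tiny_cnn <- function(encoder, x, keep_cache = FALSE, ...) {
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("tiny_cnn requires image sides divisible by 4")
  p <- encoder$params
  c1 <- conv3x3(x, p$W1, p$b1, keep_cache)
  r1 <- pmax(c1$out, 0)
  p1 <- meanpool2(r1)
  c2 <- conv3x3(p1, p$W2, p$b2, keep_cache)
  r2 <- pmax(c2$out, 0)
  p2 <- meanpool2(r2)
  f <- global_avg_pool(p2)
  out <- list(features = f)
  if (keep_cache)
    out$cache <- list(Xcol1 = c1$Xcol, mask1 = c1$out > 0, dim_r1 = dim(r1),
                      p1 = p1, Xcol2 = c2$Xcol, mask2 = c2$out > 0,
                      dim_r2 = dim(r2), dim_p2 = dim(p2), maps = r2)
  out
}

#' @param cache the cache returned by `encoder_forward(..., keep_cache = TRUE)`.
#' @param dfeat gradient of the loss with respect to the feature matrix.
#' @rdname encoder_forward
#' @export
encoder_backward <- function(encoder, cache, dfeat, ...)
  UseMethod("encoder_backward")

#' @export
encoder_backward.tiny_cnn <- function(encoder, cache, dfeat, ...) {
  p <- encoder$params
  dp2 <- global_avg_pool_backward(dfeat, cache$dim_p2)
  dr2 <- meanpool2_backward(dp2, cache$dim_r2)
  dc2 <- dr2 * cache$mask2
  g2 <- conv3x3_backward(dc2, cache$Xcol2, p$W2, encoder$channels[1])
  dr1 <- meanpool2_backward(g2$dx, cache$dim_r1)
  dc1 <- dr1 * cache$mask1
  g1 <- conv3x3_backward(dc1, cache$Xcol1, p$W1, encoder$in_channels)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
}

# In-place-style SGD step over a named list of parameter arrays.
sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  params
}

# Gradient of the classifier logit with respect to the post-ReLU maps of
# the last convolution (the Grad-CAM target layer): the logit feeds back
# through global average pooling and the 2x2 mean pool only.
last_conv_grads <- function(encoder, cache, head_w) {
  B <- cache$dim_p2[4]
  dfeat <- matrix(head_w, nrow = B, ncol = length(head_w), byrow = TRUE)
  dp2 <- global_avg_pool_backward(dfeat, cache$dim_p2)
  meanpool2_backward(dp2, cache$dim_r2)
}
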