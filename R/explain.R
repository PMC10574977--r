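#' Extract penultimate-layer embeddings
#'
#' Returns the model outputs immediately before the classification head —
#' the representation carrying the most class-semantic information — one
#' row per image, deterministic in inference mode. These embeddings feed
#' cluster visualizations (e.g. an external t-SNE/UMAP run) and the
#' separation statistics used in tests.
#'
#' @param model a `trustauc_fit`, a [select_model()] snapshot, or a bare
#'   encoder.
#' @param images image array `(H, W, 1, n)` or an `image_dataset`.
#' @return numeric `n x d` matrix.
#' @export
extract_embeddings <- function(model, images) {
  enc <- if (inherits(model, c("trustauc_fit", "trustauc_snapshot")))
    model$encoder else model
  if (is.null(enc$feature_dim))
    stop("model exposes no penultimate feature layer")
  x <- if (inherits(images, "image_dataset")) load_images(images) else images
  n <- dim(x)[4]
  out <- matrix(0, n, enc$feature_dim)
  for (i0 in seq(1L, n, by = 256L)) {
    i1 <- min(i0 + 255L, n)
    out[i0:i1, ] <- encoder_forward(enc, x[, , , i0:i1, drop = FALSE])$features
  }
  out
}

#' Grad-CAM core: weighted, rectified, normalized activation map
#'
#' Given a target layer's spatial feature maps and the gradients of the
#' class score with respect to them, computes the per-channel weights as
#' the spatial mean of the gradients, forms the weighted channel sum,
#' rectifies it with ReLU, bilinearly upsamples to the requested side and
#' min-max normalizes to `[0, 1]` (an all-zero map stays all-zero).
#'
#' @param maps array `(h, w, k)` of feature maps.
#' @param grads array `(h, w, k)` of score gradients, same shape.
#' @param out_side side of the output heatmap.
#' @return `out_side x out_side` matrix in `[0, 1]`.
#' @export
cam_from_grads <- function(maps, grads, out_side) {
  stopifnot(length(dim(maps)) == 3, all(dim(maps) == dim(grads)))
  k <- dim(maps)[3]
  w <- apply(grads, 3, mean)                     # per-channel weight
  cam <- matrix(0, dim(maps)[1], dim(maps)[2])
  for (ch in seq_len(k)) cam <- cam + w[ch] * maps[, , ch]
  cam <- pmax(cam, 0)                            # ReLU
  cam <- bilinear_resize(cam, out_side, out_side)
  cam <- pmax(cam, 0)                            # interpolation guard
  mx <- max(cam); mn <- min(cam)
  if (mx > mn) cam <- (cam - mn) / (mx - mn)
  else if (mx > 0) cam <- cam / mx             # constant positive map
  cam
}

#' Grad-CAM heatmap for one image
#'
#' Explains a classifier's positive-class score on one image: gradients
#' of the (pre-sigmoid) class score with respect to the post-ReLU feature
#' maps of the last convolution layer — the deepest layer that still
#' preserves spatial information — are spatially averaged into channel
#' weights, the weighted map sum is rectified, upsampled to the input
#' resolution and min-max normalized.
#'
#' @param model a `trustauc_fit` or [select_model()] snapshot built on a
#'   [tiny_cnn()] encoder.
#' @param image numeric matrix (single grayscale image in `[0, 1]`).
#' @return matrix of the image's size with values in `[0, 1]`; attribute
#'   `"raw"` holds the pre-normalization (rectified) map at feature-map
#'   resolution.
#' @export
grad_cam <- function(model, image) {
  enc <- if (inherits(model, c("trustauc_fit", "trustauc_snapshot")))
    model$encoder else stop("grad_cam needs a fitted model with a head")
  if (!inherits(enc, "tiny_cnn"))
    stop("target layer resolution is implemented for tiny_cnn encoders")
  head <- model$head
  side <- nrow(image)
  x <- array(image, c(side, ncol(image), 1L, 1L))
  fw <- encoder_forward(enc, x, keep_cache = TRUE)
  maps <- fw$cache$maps[, , , 1L]                       # (h, w, k) post-ReLU
  grads <- last_conv_grads(enc, fw$cache, head$w)[, , , 1L]
  out <- cam_from_grads(maps, grads, side)
  attr(out, "raw") <- {
    w <- apply(grads, 3, mean)
    raw <- matrix(0, dim(maps)[1], dim(maps)[2])
    for (ch in seq_len(dim(maps)[3])) raw <- raw + w[ch] * maps[, , ch]
    pmax(raw, 0)
  }
  out
}

#' Write a heatmap (and optional overlay) as PNG
#'
#' @param heatmap matrix in `[0, 1]` from [grad_cam()].
#' @param path output PNG path (grayscale heatmap).
#' @param image optional source image; when given, a simple overlay
#'   (image dimmed, heatmap added) is written next to `path` with suffix
#'   `_overlay.png`.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(heatmap, path, image = NULL) {
  png::writePNG(clip01(unclass(heatmap)), target = path)
  if (!is.null(image)) {
    ov <- clip01(0.5 * image + 0.5 * unclass(heatmap))
    png::writePNG(ov, target = sub("\\.png$", "_overlay.png", path))
  }
  invisible(path)
}

#' Embedding class-separation statistic
#'
#' Ratio of the between-class centroid distance to the mean within-class
#' distance-to-centroid; larger values mean tighter, better-separated
#' class clusters in the embedding space.
#'
#' @param embeddings `n x d` matrix.
#' @param labels 0/1 vector.
#' @return a single non-negative number.
#' @export
embedding_separation <- function(embeddings, labels) {
  mp <- colMeans(embeddings[labels == 1, , drop = FALSE])
  mn <- colMeans(embeddings[labels == 0, , drop = FALSE])
  between <- sqrt(sum((mp - mn)^2))
  within <- mean(c(
    sqrt(rowSums((embeddings[labels == 1, , drop = FALSE] -
                    matrix(mp, sum(labels == 1), length(mp), byrow = TRUE))^2)),
    sqrt(rowSums((embeddings[labels == 0, , drop = FALSE] -
                    matrix(mn, sum(labels == 0), length(mn), byrow = TRUE))^2))))
  if (within == 0) Inf else between / within
}
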