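#' Augmentation policy for contrastive view generation
#'
#' A grayscale-safe subset of the canonical contrastive augmentation suite:
#' random resized crop, horizontal flip, brightness/contrast jitter, and
#' optional Gaussian blur. The identity policy (`crop_scale = c(1, 1)`,
#' `flip_prob = 0`, `intensity_jitter = 0`, `blur_sigma = NULL`) is a
#' strict no-op, which the view generator's tests rely on.
#'
#' @param crop_scale `c(min, max)` fraction of image area retained by the
#'   random crop before resizing back to the original side.
#' @param flip_prob probability of a horizontal flip.
#' @param intensity_jitter maximum absolute brightness shift and maximum
#'   relative contrast change applied per view.
#' @param blur_sigma `c(min, max)` Gaussian blur sigma in pixels, or
#'   `NULL` to disable.
#' @return an object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(crop_scale = c(0.5, 1.0), flip_prob = 0.5,
                                intensity_jitter = 0.4, blur_sigma = NULL) {
  stopifnot(length(crop_scale) == 2, crop_scale[1] > 0,
            crop_scale[1] <= crop_scale[2], crop_scale[2] <= 1,
            flip_prob >= 0, flip_prob <= 1, intensity_jitter >= 0)
  if (!is.null(blur_sigma))
    stopifnot(length(blur_sigma) == 2, blur_sigma[1] <= blur_sigma[2],
              blur_sigma[1] > 0)
  structure(list(crop_scale = crop_scale, flip_prob = flip_prob,
                 intensity_jitter = intensity_jitter, blur_sigma = blur_sigma),
            class = "augmentation_policy")
}

identity_policy <- function()
  augmentation_policy(crop_scale = c(1, 1), flip_prob = 0,
                      intensity_jitter = 0, blur_sigma = NULL)

gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  n <- nrow(img)
  # separable blur with edge replication
  ext <- function(m) m[c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  m <- ext(img)
  rows <- vapply(seq_len(n), function(i)
    colSums(m[i:(i + 2L * r), , drop = FALSE] * k), numeric(ncol(img)))
  m <- ext(t(rows))
  t(vapply(seq_len(ncol(img)), function(i)
    colSums(m[i:(i + 2L * r), , drop = FALSE] * k), numeric(n)))
}

augment_once <- function(img, policy) {
  side <- nrow(img)
  out <- img
  # random resized crop (area scale, aspect kept square)
  if (policy$crop_scale[1] < 1 || policy$crop_scale[2] < 1) {
    area <- stats::runif(1, policy$crop_scale[1], policy$crop_scale[2])
    cs <- max(4L, round(side * sqrt(area)))
    cs <- min(cs, side)
    if (cs < side) {
      x0 <- sample.int(side - cs + 1L, 1L)
      y0 <- sample.int(side - cs + 1L, 1L)
      out <- bilinear_resize(out[x0:(x0 + cs - 1L), y0:(y0 + cs - 1L)], side, side)
    }
  }
  if (policy$flip_prob > 0 && stats::runif(1) < policy$flip_prob)
    out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  if (policy$intensity_jitter > 0) {
    shift <- stats::runif(1, -policy$intensity_jitter, policy$intensity_jitter)
    scale <- 1 + stats::runif(1, -policy$intensity_jitter, policy$intensity_jitter)
    out <- (out - mean(out)) * scale + mean(out) + shift
  }
  if (!is.null(policy$blur_sigma)) {
    s <- stats::runif(1, policy$blur_sigma[1], policy$blur_sigma[2])
    out <- gaussian_blur(out, s)
  }
  clip01(out)
}

#' Generate two augmented views of one image
#'
#' Independently samples two stochastic augmentations of the same source
#' image — the positive pair of the contrastive objective. Output
#' dimensions equal input dimensions; pixel values stay in `[0, 1]` by
#' clipping.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param policy an [augmentation_policy()].
#' @param seed optional RNG seed (same seed reproduces the same pair).
#' @return list with matrices `view_a` and `view_b`.
#' @export
make_views <- function(image, policy = augmentation_policy(), seed = NULL) {
  stopifnot(inherits(policy, "augmentation_policy"))
  with_seed(seed, list(view_a = augment_once(image, policy),
                       view_b = augment_once(image, policy)))
}
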