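# Shared numerical helpers.

clip01 <- function(x) pmin(pmax(x, 0), 1)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Bilinear resize of a numeric matrix
#'
#' Resizes a 2-D intensity map with bilinear interpolation, mapping the
#' corners of the source grid onto the corners of the target grid
#' (align-corners convention, so same-size resizing is the identity).
#'
#' @param x numeric matrix.
#' @param out_h,out_w target dimensions (positive integers).
#' @return numeric matrix of dimension `out_h` x `out_w`.
#' @keywords internal
bilinear_resize <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  stopifnot(h >= 1, w >= 1, out_h >= 1, out_w >= 1)
  if (h == out_h && w == out_w) return(x)
  ri <- if (out_h == 1) rep((h + 1) / 2, 1L) else 1 + (seq_len(out_h) - 1) * (h - 1) / (out_h - 1)
  ci <- if (out_w == 1) rep((w + 1) / 2, 1L) else 1 + (seq_len(out_w) - 1) * (w - 1) / (out_w - 1)
  r0 <- pmin(floor(ri), h - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(ci), w - 1L); c0 <- pmax(c0, 1L)
  fr <- ri - r0; fc <- ci - c0
  # Four corner gathers, combined with outer-product weights.
  a <- x[r0, c0, drop = FALSE]; b <- x[r0 + 1L, c0, drop = FALSE]
  d <- x[r0, c0 + 1L, drop = FALSE]; e <- x[r0 + 1L, c0 + 1L, drop = FALSE]
  wr <- matrix(fr, out_h, out_w)
  wc <- matrix(fc, out_h, out_w, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + d * (1 - wr) * wc + e * wr * wc
}

# Run `expr` under a temporarily-set RNG seed, restoring the caller's RNG
# state afterwards so library internals never perturb user randomness.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Derive a child seed from a base seed and a stage label, staying well below
# .Machine$integer.max.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147480000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
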