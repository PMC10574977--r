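#' Image dataset backed by a manifest
#'
#' An `image_dataset` is a thin S3 wrapper around a data frame of records
#' with columns `id`, `path`, `label` (0 = negative, 1 = positive) and
#' `split` (one of `"train"`, `"val"`, `"test"`), plus the working square
#' image side in pixels. Images stay on disk; [load_images()] materializes
#' them as an array.
#'
#' @param records data frame with columns `id`, `path`, `label`, `split`.
#' @param image_side working resolution (square side, pixels).
#' @param validate check invariants (unique ids, labels in \{0,1\}).
#' @return an object of class `image_dataset`.
#' @export
image_dataset <- function(records, image_side = 32L, validate = TRUE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (validate) {
    need <- c("id", "path", "label", "split")
    miss <- setdiff(need, names(records))
    if (length(miss))
      stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
    records$id <- as.character(records$id)
    records$label <- suppressWarnings(as.integer(records$label))
    if (anyNA(records$label) || !all(records$label %in% c(0L, 1L)))
      stop("labels must be exactly 0 (negative) or 1 (positive)")
    if (anyDuplicated(records$id))
      stop("record ids must be unique within a dataset")
    bad <- setdiff(unique(records$split), c("train", "val", "test"))
    if (length(bad))
      stop("unknown split tag(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(records = records[, c("id", "path", "label", "split")],
         image_side = as.integer(image_side)),
    class = "image_dataset")
}

#' @export
print.image_dataset <- function(x, ...) {
  cat("<image_dataset> ", nrow(x$records), " records, side ",
      x$image_side, "px\n", sep = "")
  tab <- table(split = x$records$split, label = factor(x$records$label, c(0, 1)))
  print(tab)
  invisible(x)
}

#' Per-split class counts
#' @param dataset an `image_dataset`.
#' @param split optional split tag to restrict to.
#' @return named vector `c(n_neg, n_pos)`.
#' @export
class_counts <- function(dataset, split = NULL) {
  rec <- dataset$records
  if (!is.null(split)) rec <- rec[rec$split == split, , drop = FALSE]
  c(n_neg = sum(rec$label == 0L), n_pos = sum(rec$label == 1L))
}

subset_dataset <- function(dataset, keep) {
  image_dataset(dataset$records[keep, , drop = FALSE],
                image_side = dataset$image_side, validate = FALSE)
}

#' Read / write a dataset manifest
#'
#' The manifest is a UTF-8 CSV with header `id,path,label,split`. Reading
#' validates the label domain and id uniqueness; with `strict = TRUE` each
#' image path must also exist on disk. Relative paths are resolved against
#' the manifest's directory.
#'
#' @param path manifest CSV path.
#' @param image_side working resolution recorded on the returned dataset.
#' @param strict verify that every image file exists.
#' @return [read_manifest()]: an `image_dataset`; [write_manifest()]: the
#'   manifest path, invisibly.
#' @export
read_manifest <- function(path, image_side = 32L, strict = FALSE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "path", "label", "split")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("manifest is missing required column(s): ", paste(miss, collapse = ", "))
  lab <- suppressWarnings(as.integer(rec$label))
  if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
    stop("manifest labels must be 0 or 1")
  rec$label <- lab
  rel <- !grepl("^(/|[A-Za-z]:)", rec$path)
  rec$path[rel] <- file.path(dirname(path), rec$path[rel])
  if (strict) {
    gone <- rec$path[!file.exists(rec$path)]
    if (length(gone))
      stop("image file(s) missing: ", paste(utils::head(gone, 3), collapse = ", "))
  }
  image_dataset(rec, image_side = image_side)
}

#' @param dataset an `image_dataset`.
#' @rdname read_manifest
#' @export
write_manifest <- function(dataset, path) {
  utils::write.csv(dataset$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Specification of a synthetic imbalanced image dataset
#'
#' Describes a two-class set of square grayscale images emulating a small,
#' heavily imbalanced radiograph collection: negatives are smooth noise
#' fields, positives additionally carry one soft Gaussian-profile bright
#' blob at a random location — a controllable, localized class signal that
#' saliency maps can later be checked against. Defaults mirror a roughly
#' 6.4:1 negative:positive training imbalance.
#'
#' @param n_neg,n_pos class counts.
#' @param image_side square side in pixels.
#' @param signal_amplitude peak added intensity of the positive-class blob
#'   (0 makes the classes statistically indistinguishable).
#' @param noise_sd standard deviation of per-pixel Gaussian noise.
#' @param blob_radius_range `c(min, max)` blob radius in pixels.
#' @param split split tag assigned to every generated record.
#' @param seed RNG seed; generation is bitwise deterministic given the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_neg = 640L, n_pos = 100L, image_side = 32L,
                           signal_amplitude = 0.5, noise_sd = 0.1,
                           blob_radius_range = c(4, 8), split = "train",
                           seed = 1L) {
  stopifnot(n_neg >= 0, n_pos >= 0, image_side >= 4,
            signal_amplitude >= 0, noise_sd >= 0,
            length(blob_radius_range) == 2,
            blob_radius_range[1] <= blob_radius_range[2])
  structure(list(n_neg = as.integer(n_neg), n_pos = as.integer(n_pos),
                 image_side = as.integer(image_side),
                 signal_amplitude = signal_amplitude, noise_sd = noise_sd,
                 blob_radius_range = blob_radius_range, split = split,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# One synthetic frame: flat mid-gray field + Gaussian pixel noise, plus an
# additive radial-Gaussian blob for positives. Returns list(img, blob):
# blob carries the planted center/radius for localization checks.
synth_image <- function(side, positive, amplitude, noise_sd, radius_range) {
  img <- matrix(0.4 + stats::rnorm(side * side, sd = noise_sd), side, side)
  blob <- NULL
  if (positive) {
    r <- stats::runif(1, radius_range[1], radius_range[2])
    m <- min(r, (side - 1) / 2)
    cx <- stats::runif(1, 1 + m, side - m)
    cy <- stats::runif(1, 1 + m, side - m)
    xs <- matrix(seq_len(side), side, side)
    ys <- matrix(seq_len(side), side, side, byrow = TRUE)
    d2 <- (xs - cx)^2 + (ys - cy)^2
    img <- img + amplitude * exp(-d2 / (2 * (r / 2)^2))
    blob <- c(cx = cx, cy = cy, r = r)
  }
  list(img = clip01(img), blob = blob)
}

#' Generate a synthetic imbalanced image dataset on disk
#'
#' Writes `n_neg + n_pos` 8-bit grayscale PNGs and a `manifest.csv` under
#' `out_dir`, fully reproducible from the spec's seed. A sidecar
#' `blobs.csv` records the planted blob center and radius of each positive
#' image so that explanation heatmaps can be scored against ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if needed).
#' @return the generated `image_dataset` (paths point into `out_dir`).
#' @export
generate_synthetic_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_neg + spec$n_pos
  if (n == 0L) stop("empty dataset: n_neg + n_pos must be positive")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  labels <- c(rep(0L, spec$n_neg), rep(1L, spec$n_pos))
  ids <- sprintf("%s_%s%05d", spec$split, ifelse(labels == 1L, "pos", "neg"),
                 c(seq_len(spec$n_neg), seq_len(spec$n_pos)))
  paths <- file.path(out_dir, paste0(ids, ".png"))
  blobs <- list()
  with_seed(spec$seed, {
    for (i in seq_len(n)) {
      fr <- synth_image(spec$image_side, labels[i] == 1L,
                        spec$signal_amplitude, spec$noise_sd,
                        spec$blob_radius_range)
      # quantize to 8 bits explicitly so regeneration is byte-identical
      png::writePNG(round(fr$img * 255) / 255, target = paths[i])
      if (!is.null(fr$blob)) blobs[[ids[i]]] <- fr$blob
    }
  })
  rec <- data.frame(id = ids, path = paths, label = labels,
                    split = spec$split, stringsAsFactors = FALSE)
  ds <- image_dataset(rec, image_side = spec$image_side)
  write_manifest(ds, file.path(out_dir, "manifest.csv"))
  if (length(blobs)) {
    bl <- do.call(rbind, blobs)
    utils::write.csv(data.frame(id = rownames(bl), bl, row.names = NULL),
                     file.path(out_dir, "blobs.csv"), row.names = FALSE)
  }
  ds
}

#' Load a dataset's images into an array
#'
#' Reads each record's image, converts to grayscale in `[0, 1]` (RGB inputs
#' are averaged across channels), and resizes to the dataset's working
#' side. Returns an array of dimension `(side, side, 1, n)` in record
#' order.
#'
#' @param dataset an `image_dataset` (or a record data frame subset).
#' @param image_side override the working side.
#' @return numeric array `(side, side, 1, n)`.
#' @export
load_images <- function(dataset, image_side = NULL) {
  rec <- dataset$records
  side <- as.integer(image_side %||% dataset$image_side)
  out <- array(0, c(side, side, 1L, nrow(rec)))
  for (i in seq_len(nrow(rec))) {
    img <- png::readPNG(rec$path[i])
    if (length(dim(img)) == 3L) img <- rowMeans(img[, , 1:3, drop = FALSE], dims = 2)
    if (!all(dim(img) == c(side, side))) img <- bilinear_resize(img, side, side)
    out[, , 1L, i] <- img
  }
  out
}

#' Balanced validation split
#'
#' Carves a class-balanced validation set out of a dataset's training
#' split, mirroring a balanced random sampling strategy: the validation
#' set holds `round(fraction * n_train)` records with (as near as
#' possible) equal per-class counts, so that validation metrics are
#' computed on a class distribution matching a balanced test set rather
#' than the skewed training distribution.
#'
#' Each class contributes `floor(val_size / 2)`; if `val_size` is odd the
#' extra slot goes to the majority class, preserving scarce positives for
#' training. A class too small to fill its quota contributes at most half
#' of its members (with a warning), so that fine-tuning always retains
#' training examples of both classes under extreme imbalance.
#'
#' @param dataset an `image_dataset` whose `train` split holds both classes.
#' @param fraction validation fraction of the training split, in (0, 1].
#' @param seed RNG seed controlling the sampled membership.
#' @return list with elements `train` and `val` (both `image_dataset`s);
#'   their record sets are disjoint and their union is the original train
#'   split.
#' @export
balanced_validation_split <- function(dataset, fraction = 0.1, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  rec <- dataset$records
  tr <- which(rec$split == "train")
  if (!length(tr)) stop("dataset has no train split")
  pos <- tr[rec$label[tr] == 1L]
  neg <- tr[rec$label[tr] == 0L]
  if (!length(pos) || !length(neg))
    stop("both classes must be present in the train split")
  val_size <- round(fraction * length(tr))
  quota <- floor(val_size / 2)
  q_pos <- quota
  q_neg <- quota + (val_size %% 2) * as.integer(length(neg) >= length(pos))
  q_pos <- q_pos + (val_size %% 2) * as.integer(length(neg) < length(pos))
  take <- function(idx, q, cls) {
    cap <- max(1L, floor(length(idx) / 2))
    if (cap < q) {
      warning("class ", cls, " has only ", length(idx),
              " members for a validation quota of ", q, "; taking ", cap,
              " to preserve training data")
      q <- cap
    }
    idx[sample.int(length(idx), q)]
  }
  sel <- with_seed(seed, c(take(neg, q_neg, "negative"), take(pos, q_pos, "positive")))
  val_rec <- rec[sel, , drop = FALSE]; val_rec$split <- "val"
  train_rec <- rec[setdiff(tr, sel), , drop = FALSE]
  list(train = image_dataset(train_rec, dataset$image_side, validate = FALSE),
       val = image_dataset(val_rec, dataset$image_side, validate = FALSE))
}

#' Stratified k-fold splits
#'
#' Partitions a dataset's records into k class-stratified folds: within
#' each class, shuffled members are dealt round-robin to folds, so
#' per-fold positive counts differ by at most one and every validation
#' fold contains positives even under heavy imbalance.
#'
#' @param dataset an `image_dataset`.
#' @param k number of folds (>= 2); each class must have >= k members.
#' @param seed RNG seed; assignments depend only on (seed, k, record ids).
#' @return list of k elements, each `list(train =, val =)` of
#'   `image_dataset`s; the k validation folds partition the dataset.
#' @export
kfold_splits <- function(dataset, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  rec <- dataset$records
  fold <- integer(nrow(rec))
  with_seed(seed, {
    for (lab in c(0L, 1L)) {
      idx <- which(rec$label == lab)
      if (length(idx) < k)
        stop("class ", lab, " has fewer than k = ", k, " members")
      fold[idx[order(stats::runif(length(idx)))]] <-
        rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    va <- rec[fold == f, , drop = FALSE]; va$split <- "val"
    tr <- rec[fold != f, , drop = FALSE]; tr$split <- "train"
    list(train = image_dataset(tr, dataset$image_side, validate = FALSE),
         val = image_dataset(va, dataset$image_side, validate = FALSE))
  })
}
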