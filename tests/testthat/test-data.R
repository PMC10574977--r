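test_that("synthetic generation honors counts and is byte-deterministic", {
  spec <- synthetic_spec(n_neg = 6, n_pos = 1, image_side = 16, seed = 3)
  d1 <- tempfile(); d2 <- tempfile()
  ds1 <- generate_synthetic_dataset(spec, d1)
  ds2 <- generate_synthetic_dataset(spec, d2)
  expect_equal(nrow(ds1$records), 7)
  expect_equal(unname(class_counts(ds1)), c(6L, 1L))
  man <- read.csv(file.path(d1, "manifest.csv"))
  expect_equal(nrow(man), 7)
  for (i in seq_len(7)) {
    expect_identical(readBin(ds1$records$path[i], "raw", 1e6),
                     readBin(ds2$records$path[i], "raw", 1e6))
  }
  expect_identical(sub(d1, "", readLines(file.path(d1, "manifest.csv")), fixed = TRUE),
                   sub(d2, "", readLines(file.path(d2, "manifest.csv")), fixed = TRUE))
  expect_error(generate_synthetic_dataset(
    synthetic_spec(n_neg = 0, n_pos = 0), tempfile()), "empty")
})

test_that("zero signal amplitude yields statistically indistinguishable classes", {
  ds <- generate_synthetic_dataset(
    synthetic_spec(n_neg = 200, n_pos = 200, image_side = 16,
                   signal_amplitude = 0, noise_sd = 0.1, seed = 9),
    tempfile())
  imgs <- load_images(ds)
  mi <- apply(imgs, 4, mean)
  fit <- suppressWarnings(glm(ds$records$label ~ mi, family = binomial()))
  auc <- roc_auc(fitted(fit), ds$records$label)
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("a strong blob signal is linearly separable from blob-region intensity", {
  dir <- tempfile()
  ds <- generate_synthetic_dataset(
    synthetic_spec(n_neg = 60, n_pos = 60, image_side = 32,
                   signal_amplitude = 0.5, noise_sd = 0.1, seed = 13),
    dir)
  imgs <- load_images(ds)
  blobs <- read.csv(file.path(dir, "blobs.csv"))
  # score every image by its mean intensity inside a central-disc-sized
  # window around the brightest pixel (class-signal oracle)
  r <- median(blobs$r)
  score <- apply(imgs, 4, function(m) {
    m <- m[, , 1]
    w <- which(m == max(m), arr.ind = TRUE)[1, ]
    xs <- pmax(1, w[1] - 2):pmin(32, w[1] + 2)
    ys <- pmax(1, w[2] - 2):pmin(32, w[2] + 2)
    mean(m[xs, ys])
  })
  half <- rep(c(TRUE, FALSE), length.out = nrow(ds$records))
  fit <- suppressWarnings(glm(ds$records$label[half] ~ score[half],
                              family = binomial()))
  held <- predict(fit, newdata = data.frame(score = score[!half]))
  expect_gt(roc_auc(held, ds$records$label[!half]), 0.95)
})

test_that("manifest roundtrip is the identity and validation rejects bad input", {
  rec <- data.frame(id = c("a", "b", "c"),
                    path = c("x1.png", "x2.png", "x3.png"),
                    label = c(0L, 1L, 0L),
                    split = c("train", "train", "test"))
  ds <- image_dataset(rec, image_side = 16)
  p <- tempfile(fileext = ".csv")
  write_manifest(ds, p)
  back <- read_manifest(p, image_side = 16)
  expect_equal(back$records$id, rec$id)
  expect_equal(back$records$label, rec$label)
  expect_equal(back$records$split, rec$split)
  expect_equal(basename(back$records$path), rec$path)

  bad <- rec; bad$label[2] <- 2L
  write.csv(bad, p, row.names = FALSE)
  expect_error(read_manifest(p), "0 or 1")
  dup <- rec; dup$id[2] <- "a"
  write.csv(dup, p, row.names = FALSE)
  expect_error(read_manifest(p), "unique")
  nolab <- rec[, c("id", "path", "split")]
  write.csv(nolab, p, row.names = FALSE)
  expect_error(read_manifest(p), "missing required column")
  write.csv(rec, p, row.names = FALSE)
  expect_error(read_manifest(p, strict = TRUE), "missing")
})

test_that("balanced validation split meets quota, disjointness and determinism", {
  rec <- data.frame(id = sprintf("r%03d", 1:120),
                    path = "unused.png",
                    label = c(rep(0L, 100), rep(1L, 20)),
                    split = "train")
  ds <- image_dataset(rec, 16)
  sp <- balanced_validation_split(ds, 0.10, seed = 4)
  expect_equal(nrow(sp$val$records), 12)
  expect_equal(unname(class_counts(sp$val)), c(6L, 6L))
  expect_length(intersect(sp$train$records$id, sp$val$records$id), 0)
  expect_setequal(c(sp$train$records$id, sp$val$records$id), rec$id)
  sp2 <- balanced_validation_split(ds, 0.10, seed = 4)
  expect_identical(sort(sp$val$records$id), sort(sp2$val$records$id))

  bal <- image_dataset(data.frame(id = sprintf("b%03d", 1:100), path = "u.png",
                                  label = rep(c(0L, 1L), each = 50),
                                  split = "train"), 16)
  sb <- balanced_validation_split(bal, 0.2, seed = 1)
  expect_equal(unname(class_counts(sb$val)), c(10L, 10L))
  expect_equal(unname(class_counts(sb$train)), c(40L, 40L))

  expect_error(balanced_validation_split(ds, 0), "fraction")
  expect_error(balanced_validation_split(ds, 1.2), "fraction")
  onecls <- image_dataset(data.frame(id = c("a", "b"), path = "u.png",
                                     label = c(0L, 0L), split = "train"), 16)
  expect_error(balanced_validation_split(onecls, 0.5), "both classes")
})

test_that("balanced split never strips a scarce class from training", {
  rec <- data.frame(id = sprintf("s%03d", 1:420), path = "u.png",
                    label = c(rep(0L, 400), rep(1L, 20)), split = "train")
  ds <- image_dataset(rec, 16)
  expect_warning(sp <- balanced_validation_split(ds, 0.10, seed = 2),
                 "preserve training data")
  expect_gte(sum(sp$train$records$label == 1), 10)
  expect_gte(sum(sp$val$records$label == 1), 1)
})

test_that("k-fold splits partition, stratify and validate preconditions", {
  rec <- data.frame(id = sprintf("k%03d", 1:100), path = "u.png",
                    label = c(rep(0L, 90), rep(1L, 10)), split = "train")
  ds <- image_dataset(rec, 16)
  folds <- kfold_splits(ds, k = 5, seed = 8)
  expect_length(folds, 5)
  val_ids <- lapply(folds, function(f) f$val$records$id)
  expect_setequal(unlist(val_ids), rec$id)
  expect_equal(sum(lengths(val_ids)), 100)      # disjoint + exhaustive
  pos_per_fold <- vapply(folds, function(f) sum(f$val$records$label == 1),
                         integer(1))
  expect_true(all(pos_per_fold == 2L))
  for (f in folds)
    expect_length(intersect(f$train$records$id, f$val$records$id), 0)
  # determinism: assignments derive from (seed, k, ids)
  folds2 <- kfold_splits(ds, k = 5, seed = 8)
  expect_identical(val_ids, lapply(folds2, function(f) f$val$records$id))

  expect_error(kfold_splits(ds, k = 1), "k must be")
  tiny <- image_dataset(data.frame(id = letters[1:6], path = "u.png",
                                   label = c(0, 0, 0, 0, 1, 1),
                                   split = "train"), 16)
  expect_error(kfold_splits(tiny, k = 5), "fewer than k")
})
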