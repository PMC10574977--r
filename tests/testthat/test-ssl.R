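test_that("view generation respects the policy contract", {
  set.seed(3)
  img <- matrix(runif(32 * 32), 32, 32)
  noop <- augmentation_policy(crop_scale = c(1, 1), flip_prob = 0,
                              intensity_jitter = 0)
  v <- make_views(img, noop, seed = 1)
  expect_identical(v$view_a, img)
  expect_identical(v$view_b, img)

  v1 <- make_views(img, augmentation_policy(), seed = 7)
  v2 <- make_views(img, augmentation_policy(), seed = 7)
  expect_identical(v1, v2)

  flip <- augmentation_policy(crop_scale = c(1, 1), flip_prob = 1,
                              intensity_jitter = 0)
  vf <- make_views(img, flip, seed = 2)
  expect_equal(vf$view_a, img[, 32:1])
  expect_equal(vf$view_b, img[, 32:1])

  expect_error(augmentation_policy(crop_scale = c(0.9, 0.5)))
})

test_that("NT-Xent matches closed forms and a brute-force enumeration", {
  for (N in c(2, 4, 8)) {
    E <- matrix(1, 2 * N, 6)
    expect_equal(nt_xent(E, tau = 0.5), log(2 * N - 1), tolerance = 1e-9)
    expect_equal(nt_xent(E, tau = 0.07), log(2 * N - 1), tolerance = 1e-9)
  }
  set.seed(11)
  for (i in 1:10) {
    E <- matrix(rnorm(8 * 16), 8, 16)
    expect_equal(nt_xent(E, 0.5), ntxent_bruteforce(E, 0.5), tolerance = 1e-6)
  }
  # permutation of whole pairs leaves the loss unchanged
  E <- matrix(rnorm(8 * 5), 8, 5)
  Eperm <- E[c(3, 4, 1, 2, 7, 8, 5, 6), ]
  expect_equal(nt_xent(E, 0.3), nt_xent(Eperm, 0.3), tolerance = 1e-12)

  expect_error(nt_xent(matrix(1, 2, 4), 0.5), "N >= 2")
  E0 <- matrix(rnorm(8 * 4), 8, 4); E0[3, ] <- 0
  expect_error(nt_xent(E0, 0.5), "zero")
})

test_that("NT-Xent is rotation invariant and rewards positive-pair similarity", {
  set.seed(5)
  E <- matrix(rnorm(12 * 6), 12, 6)
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))        # random orthogonal rotation
  expect_equal(nt_xent(E, 0.4), nt_xent(E %*% Q, 0.4), tolerance = 1e-10)

  # moving one view toward its partner strictly lowers the loss
  E2 <- E
  E2[2, ] <- E2[2, ] + 0.5 * (E2[1, ] / sqrt(sum(E2[1, ]^2)) -
                                E2[2, ] / sqrt(sum(E2[2, ]^2)))
  z1 <- E[1, ] / sqrt(sum(E[1, ]^2)); z2 <- E[2, ] / sqrt(sum(E[2, ]^2))
  z2b <- E2[2, ] / sqrt(sum(E2[2, ]^2))
  expect_gt(sum(z1 * z2b), sum(z1 * z2))        # perturbation did increase sim
  expect_lt(nt_xent(E2, 0.5), nt_xent(E, 0.5))

  # gradient agrees with central finite differences
  g <- nt_xent(E, 0.5, grad = TRUE)$grad
  for (ii in c(1, 14, 40)) {
    Ep <- E; Ep[ii] <- Ep[ii] + 1e-6
    Em <- E; Em[ii] <- Em[ii] - 1e-6
    fd <- (ntxent_bruteforce(Ep, 0.5) - ntxent_bruteforce(Em, 0.5)) / 2e-6
    expect_equal(g[ii], fd, tolerance = 1e-4)
  }
})

test_that("pre-training runs, progresses, is deterministic and label-blind", {
  ds <- generate_synthetic_dataset(
    synthetic_spec(n_neg = 40, n_pos = 24, image_side = 32,
                   signal_amplitude = 0.6, noise_sd = 0.08, seed = 21),
    tempfile())

  first8 <- trustauc:::subset_dataset(ds, seq_len(nrow(ds$records)) <= 8)
  one <- pretrain_encoder(tiny_cnn(seed = 2), first8,
                          config = ssl_config(epochs = 1, batch_pairs = 4, seed = 3))
  expect_length(one$loss_history, 1)
  expect_true(is.finite(one$loss_history))

  cfg <- ssl_config(epochs = 10, batch_pairs = 16, learning_rate = 0.1, seed = 3)
  pt <- pretrain_encoder(tiny_cnn(seed = 2), ds, augmentation_policy(), cfg)
  lh <- pt$loss_history
  expect_true(all(is.finite(lh)))
  expect_lt(mean(lh[8:10]), mean(lh[1:3]))      # training progress

  pt2 <- pretrain_encoder(tiny_cnn(seed = 2), ds, augmentation_policy(), cfg)
  expect_identical(lh, pt2$loss_history)

  # labels are never read: a label-free record table works
  blind <- ds
  blind$records$label <- NULL
  expect_no_error(pretrain_encoder(tiny_cnn(seed = 2), blind,
                                   config = ssl_config(epochs = 1,
                                                       batch_pairs = 8,
                                                       seed = 1)))

  expect_error(pretrain_encoder(tiny_cnn(), trustauc:::subset_dataset(ds, FALSE),
                                config = cfg), "empty")
  expect_error(pretrain_encoder(tiny_cnn(), ds,
                                config = ssl_config(batch_pairs = 100)),
               "exceeds")
})
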