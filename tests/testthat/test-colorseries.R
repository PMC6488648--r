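# Registration, white balance, Lab conversion, texture features,
# SOM labelling, segmentation and the colour series.

test_that("phase correlation recovers known integer shifts", {
  fx <- fixture_scene()
  expect_equal(unname(estimate_shift(fx$frame, fx$frame)$shift), c(0, 0))

  tr <- scene_truth(fx$region, redness_a = 8, frame_shift = c(5, -3))
  fs <- generate_reef_frame(tr, seed = 6)
  est <- estimate_shift(fs, fx$frame)
  expect_equal(unname(est$shift), c(5, -3), tolerance = 0.5)
  expect_gt(est$quality, 0.1)
})

test_that("unrelated noise frames signal alignment failure", {
  set.seed(8)
  n1 <- reef_frame(array(runif(128 * 128 * 3), c(128, 128, 3)))
  n2 <- reef_frame(array(runif(128 * 128 * 3), c(128, 128, 3)))
  reg <- register_frame(n1, n2)
  expect_false(reg$success)
  expect_lt(reg$quality, 0.05)
  # a blank frame fails too
  blank <- reef_frame(array(0.5, c(128, 128, 3)))
  expect_false(register_frame(blank, n2)$success)
})

test_that("registered frames flag wrapped border pixels invalid", {
  fx <- fixture_scene()
  tr <- scene_truth(fx$region, redness_a = 8, frame_shift = c(4, -2))
  fs <- generate_reef_frame(tr, seed = 6)
  reg <- register_frame(fs, fx$frame)
  expect_true(reg$success)
  v <- reg$frame$valid
  expect_false(all(v))
  expect_equal(sum(!v), 4 * nrow(v) + 2 * ncol(v) - 8)
})

test_that("white balance scales channels, clips, and preserves differences", {
  f <- reef_frame(array(100 / 255, c(4, 4, 3)))
  expect_equal(white_balance(f, c(1, 1, 1))$data, f$data)
  wb <- white_balance(f, c(2, 1, 1))
  expect_equal(wb$data[1, 1, ], c(200, 100, 100) / 255)
  expect_error(white_balance(f, c(0, 1, 1)), "positive")

  # linearity: the same gains keep frame-to-frame differences proportional
  f2 <- reef_frame(array(50 / 255, c(4, 4, 3)))
  d_raw <- f$data - f2$data
  d_wb <- white_balance(f, c(1.5, 1.2, 1))$data -
    white_balance(f2, c(1.5, 1.2, 1))$data
  expect_equal(d_wb[1, 1, ], d_raw[1, 1, ] * c(1.5, 1.2, 1))
})

test_that("sRGB/D65 Lab conversion matches reference values and round-trips", {
  gray <- rgb_to_lab(array(128 / 255, c(1, 1, 3)))
  expect_equal(gray[1, 1, 2], 0, tolerance = 0.01)
  expect_equal(gray[1, 1, 3], 0, tolerance = 0.01)

  red <- rgb_to_lab(array(c(1, 0, 0), c(1, 1, 3)))
  expect_equal(red[1, 1, 2], 80.1, tolerance = 0.01 / 8)

  # independent oracle: base R colorimetric conversion (different
  # implementation, slightly different constants)
  set.seed(1)
  px <- array(runif(30), c(10, 1, 3))
  ours <- matrix(rgb_to_lab(px), ncol = 3)
  base_r <- grDevices::convertColor(matrix(px, ncol = 3), "sRGB", "Lab")
  expect_lt(max(abs(ours - base_r)), 0.35)

  # Lab -> RGB -> Lab round trip
  lab <- array(c(55, 12, -4), c(1, 1, 3))
  rt <- rgb_to_lab(lab_to_rgb(lab))
  expect_lt(max(abs(rt - lab)), 0.01)
})

test_that("Gabor features have the promised dimension and selectivity", {
  const <- matrix(0.5, 64, 64)
  bank <- gabor_bank(wavelengths = c(6, 12), n_orientations = 4)
  f <- extract_gabor_features(const, bank)
  expect_equal(dim(f), c(64, 64, 2))
  expect_lt(max(abs(f)), 1e-8)      # flat image: zero band-pass energy

  bank_full <- gabor_bank(wavelengths = 8, n_orientations = 2,
                          pool_orientations = FALSE, smooth_sd = 0)
  expect_equal(dim(extract_gabor_features(const, bank_full))[3], 2)

  # gratings excite the orientation channel orthogonal to their stripes
  g <- expand.grid(y = 1:64, x = 1:64)
  vert_stripes <- matrix(0.5 + 0.4 * sin(2 * pi * g$x / 8), 64, 64)
  horz_stripes <- matrix(0.5 + 0.4 * sin(2 * pi * g$y / 8), 64, 64)
  fv <- extract_gabor_features(vert_stripes, bank_full)
  fh <- extract_gabor_features(horz_stripes, bank_full)
  ctr <- 24:40
  # channel 1: orientation 0 (horizontal wave vector -> vertical stripes)
  expect_gt(mean(fv[ctr, ctr, 1]), 3 * mean(fv[ctr, ctr, 2]))
  expect_gt(mean(fh[ctr, ctr, 2]), 3 * mean(fh[ctr, ctr, 1]))

  expect_error(gabor_bank(wavelengths = numeric()), "empty")
})

test_that("SOM labeller separates separable clouds and is deterministic", {
  set.seed(3)
  n <- 1500
  X <- rbind(matrix(rnorm(n * 4, 0, 1), ncol = 4),
             matrix(rnorm(n * 4, 6, 1), ncol = 4))
  y <- rep(c("background", "coral"), each = n)
  hold <- sample(2 * n, 500)
  lab <- train_pixel_labeller(X[-hold, ], y[-hold], seed = 11)
  acc <- mean(predict_pixels(lab, X[hold, , drop = FALSE]) == y[hold])
  expect_gte(acc, 0.99)

  # identical feature distributions: accuracy collapses to chance
  X2 <- matrix(rnorm(2 * n * 4), ncol = 4)
  lab2 <- train_pixel_labeller(X2[-hold, ], y[-hold], seed = 11)
  acc2 <- mean(predict_pixels(lab2, X2[hold, , drop = FALSE]) == y[hold])
  expect_lt(abs(acc2 - 0.5), 0.1)

  # retraining with the same seed reproduces the codebook
  lab3 <- train_pixel_labeller(X[-hold, ], y[-hold], seed = 11)
  expect_identical(lab$codes, lab3$codes)
  expect_identical(lab$node_class, lab3$node_class)

  expect_error(train_pixel_labeller(X, rep("coral", nrow(X))), "2 classes")
})

test_that("texture segmentation recovers the synthetic coral region", {
  fx <- fixture_scene()
  lab <- fixture_labeller()
  mask <- segment_coral(fx$frame, lab)
  expect_equal(dim(mask), dim(fx$region))
  iou <- sum(mask & fx$region) / sum(mask | fx$region)
  expect_gte(iou, 0.9)

  # an all-background frame yields a near-empty mask
  bg_truth <- scene_truth(matrix(FALSE, 192, 192), redness_a = 0)
  bg_frame <- generate_reef_frame(bg_truth, seed = 9)
  mask_bg <- segment_coral(bg_frame, lab)
  expect_lte(mean(mask_bg), 0.05)
})

test_that("mean_color equals the brute-force masked mean", {
  lab <- array(0, c(4, 4, 3))
  lab[, , 1] <- 50
  lab[, , 2] <- c(rep(0, 8), rep(10, 8))   # half a*=0, half a*=10
  lab[, , 3] <- 1
  expect_equal(unname(mean_color(lab)["a"]), 5)

  u <- array(rep(c(42, 7, -3), each = 6), c(2, 3, 3))
  m <- matrix(c(TRUE, rep(FALSE, 5)), 2, 3)
  expect_equal(unname(mean_color(u, m)), c(42, 7, -3), ignore_attr = TRUE)

  set.seed(5)
  r <- array(rnorm(12 * 12 * 3), c(12, 12, 3))
  mk <- matrix(runif(144) > 0.5, 12, 12)
  got <- mean_color(r, mk)
  brute <- c(0, 0, 0); n <- 0
  for (y in 1:12) for (x in 1:12) if (mk[y, x]) {
    brute <- brute + r[y, x, ]; n <- n + 1
  }
  expect_equal(unname(got), brute / n, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(got, "n_px"), n)

  # full mask reproduces the all-pixel mean (the masked mean collapses to
  # the full-image mean in that limit)
  expect_equal(mean_color(r, matrix(TRUE, 12, 12)), mean_color(r),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(mean_color(r, matrix(FALSE, 12, 12)), "empty mask")
})

test_that("the colour series tracks the injected redness and records gaps", {
  seqd <- generate_sequence(8, color_trajectory = seq(0, 10, length.out = 8),
                            activity_trajectory = 0.4, jitter_sd = 1,
                            missing_fraction = 0, seed = 31,
                            width = 192, height = 192, n_polyps = 5)
  feats <- extract_gabor_features(seqd$frames[[1]])
  labv <- rep(NA_character_, length(seqd$region))
  set.seed(6)
  idx <- sample(length(seqd$region), 6000)
  labv[idx] <- ifelse(seqd$region[idx], "coral", "background")
  lab <- train_pixel_labeller(feature_matrix(feats), labv, seed = 8)

  cs <- color_series(seqd$frames, lab)
  ok <- cs$status == "ok"
  expect_true(all(ok))
  truth <- seq(0, 10, length.out = 8)
  expect_gt(cor(cs$xi_a, truth), 0.95)

  # dropped frames appear as missing timestamps in the series
  seqd2 <- generate_sequence(10, color_trajectory = 5, missing_fraction = 0.3,
                             seed = 32, width = 192, height = 192,
                             n_polyps = 5)
  cs2 <- color_series(seqd2$frames, lab)
  s2 <- as_series(cs2)
  expect_false(any(seqd2$dropped_times %in% s2$time_h))
})
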