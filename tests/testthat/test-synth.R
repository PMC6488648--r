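# Synthetic scene, signal and annotation generators.

test_that("frame rendering is deterministic and honours the requested redness", {
  region <- make_coral_region(160, 160, coverage = 0.5, seed = 7)
  t0 <- scene_truth(region, redness_a = 0)
  t15 <- scene_truth(region, redness_a = 15)
  f0a <- generate_reef_frame(t0, seed = 3)
  f0b <- generate_reef_frame(t0, seed = 3)
  expect_identical(f0a$data, f0b$data)
  f0c <- generate_reef_frame(t0, seed = 4)
  expect_false(identical(f0a$data, f0c$data))

  # measured with the independent colour oracle: masked mean a*
  f15 <- generate_reef_frame(t15, seed = 3)
  a0 <- mean_color(rgb_to_lab(f0a), region)["a"]
  a15 <- mean_color(rgb_to_lab(f15), region)["a"]
  expect_equal(unname(a15 - a0), 15, tolerance = 1 / 15)
})

test_that("a scene without polyps renders and carries zero true activity", {
  region <- make_coral_region(96, 96, coverage = 0.5, seed = 2)
  tr <- scene_truth(region, redness_a = 5)
  expect_equal(nrow(tr$polyp_centres), 0)
  f <- generate_reef_frame(tr, seed = 1)
  expect_equal(dim(f$data), c(96, 96, 3))
})

test_that("polyp centres outside the raster or region are rejected", {
  region <- matrix(FALSE, 64, 64); region[20:50, 20:50] <- TRUE
  expect_error(scene_truth(region, data.frame(x = 99, y = 5, state = "active")),
               "outside")
  expect_error(scene_truth(region, data.frame(x = 5, y = 5, state = "active")),
               "outside the coral region")
  expect_silent(scene_truth(region, data.frame(x = 30, y = 30,
                                               state = "active")))
})

test_that("sequences have hourly stamps, recorded shifts and binomial activity", {
  seqd <- generate_sequence(12, activity_trajectory = 0.5, jitter_sd = 0,
                            missing_fraction = 0, seed = 9, width = 224,
                            height = 224, n_polyps = 10)
  ts <- vapply(seqd$frames, function(f) f$timestamp, numeric(1))
  expect_equal(ts, 0:11)
  expect_length(seqd$dropped_times, 0)
  shifts <- t(vapply(seqd$truths, function(t) t$frame_shift, integer(2)))
  expect_true(all(shifts == 0L))

  # per-frame true active fraction stays within binomial sampling error
  frac <- vapply(seqd$truths, function(t) mean(t$polyp_centres$state == "active"),
                 numeric(1))
  n_tot <- 12 * 10
  p_hat <- mean(frac)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n_tot) + 1e-9)
})

test_that("missing frames are removed, not blanked, and leave gaps", {
  seqd <- generate_sequence(20, missing_fraction = 0.25, seed = 5,
                            width = 192, height = 192, n_polyps = 6)
  expect_length(seqd$frames, 15)
  expect_length(seqd$dropped_times, 5)
  ts <- vapply(seqd$frames, function(f) f$timestamp, numeric(1))
  expect_setequal(c(ts, seqd$dropped_times), 0:19)
})

test_that("sensor series follow trend + components and honour gaps", {
  # no components, no noise: exactly the trend
  sp <- signal_spec(trend = data.frame(time_h = c(0, 48), value = c(1, 3)))
  s <- generate_sensor_series(sp, 48, seed = 1)
  expect_equal(s$value, 1 + 2 * s$time_h / 48, tolerance = 1e-12)

  # a pure 24 h tone: autocorrelation at lag 24 h is ~1
  sp2 <- signal_spec(components = data.frame(period = 24, amplitude = 1,
                                             phase = 0))
  s2 <- generate_sensor_series(sp2, 24 * 20, seed = 1)
  v <- s2$value
  r24 <- cor(v[1:(length(v) - 24)], v[25:length(v)])
  expect_gt(r24, 0.999)

  # gap intervals have no measurements at all
  sp3 <- signal_spec(trend = data.frame(time_h = 0, value = 2),
                     gaps = list(c(10, 20)))
  s3 <- generate_sensor_series(sp3, 48, seed = 1)
  expect_false(any(s3$time_h >= 10 & s3$time_h <= 20))
})

test_that("AR1 noise in sensor series has the requested persistence", {
  sp <- signal_spec(ar1 = 0.8, noise_sd = 1, sampling_interval_min = 60)
  s <- generate_sensor_series(sp, 5000, seed = 42)
  v <- s$value
  r1 <- cor(v[-1], v[-length(v)])
  expect_equal(r1, 0.8, tolerance = 3 / sqrt(length(v)) / (1 - 0.8^2))
})

test_that("a single-period series puts its periodogram maximum at that period", {
  for (P in c(12.4, 24)) {
    sp <- signal_spec(components = data.frame(period = P, amplitude = 1,
                                              phase = 0.3),
                      ar1 = 0, noise_sd = 0.1)
    s <- generate_sensor_series(sp, 24 * 40, seed = 11)
    pg <- stats::spec.pgram(stats::ts(s$value, deltat = 1), plot = FALSE,
                            taper = 0)
    p_hat <- 1 / pg$freq[which.max(pg$spec)]
    grid_step <- abs(diff(1 / pg$freq[c(which.max(pg$spec),
                                        which.max(pg$spec) + 1L)]))
    expect_lt(abs(p_hat - P), grid_step + 1e-9)
  }
})

test_that("annotation noise model gives the requested flip rate and jitter", {
  region <- make_coral_region(320, 320, coverage = 0.6, seed = 4)
  seqd <- generate_sequence(6, seed = 13, width = 320, height = 320,
                            n_polyps = 12, jitter_sd = 0)
  # error-free annotator reproduces the truth exactly
  a0 <- generate_annotations(seqd$truths, 0, 0, seed = 1)
  truth_all <- do.call(rbind, lapply(seqd$truths, function(t)
    cbind(t$polyp_centres, image = t$id)))
  expect_equal(a0$x, truth_all$x)
  expect_equal(a0$class, truth_all$state)

  # two error-free annotators agree perfectly
  b0 <- generate_annotations(seqd$truths, 0, 0, annotator = "B", seed = 2)
  expect_equal(as.numeric(observer_agreement(a0, b0, match_radius = 5)), 1)

  # flip rate 0.1 produces ~10% label disagreement with the truth
  a1 <- generate_annotations(seqd$truths, 0.1, 0, seed = 3)
  dis <- mean(a1$class != truth_all$state)
  n <- nrow(truth_all)
  expect_lt(abs(dis - 0.1), 3 * sqrt(0.1 * 0.9 / n) + 1e-9)
})
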