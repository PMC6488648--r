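# Morlet CWT, bias correction, red-noise significance, global spectra.

test_that("a constant series carries (numerically) no wavelet power", {
  s <- regular_series(0, 1, rep(3.7, 256))
  w <- cwt_morlet(s)
  expect_lt(max(w$power), 1e-20)
})

test_that("sinusoids peak at their period in the global spectrum", {
  for (P in c(12.4, 24)) {
    n <- 1024
    s <- regular_series(0, 1, sin(2 * pi * (0:(n - 1)) / P))
    w <- cwt_morlet(s)
    g <- global_spectrum(w)
    p_hat <- g$period[which.max(g$power)]
    expect_lt(abs(log2(p_hat / P)), w$dj + 1e-9)   # within one scale step
  }
})

test_that("the variance identity holds to within 10%", {
  set.seed(21)
  s <- regular_series(0, 1, rnorm(512) + sin(2 * pi * (0:511) / 24))
  w <- cwt_morlet(s)
  est <- sum(w$power_bc) * w$dj * w$dt / (reefpulse:::morlet_cdelta * w$n)
  expect_equal(est, w$variance, tolerance = 0.1)
})

test_that("bias correction equalizes equal-amplitude tones across scales", {
  n <- 2048
  t <- 0:(n - 1)
  s <- regular_series(0, 1, sin(2 * pi * t / 12) + sin(2 * pi * t / 48))
  w <- cwt_morlet(s)
  g_bc <- global_spectrum(w, bias_corrected = TRUE)
  g_raw <- global_spectrum(w, bias_corrected = FALSE)
  near <- function(g, P) max(g$power[abs(log2(g$period / P)) < 0.3])
  # corrected peaks agree within 15%
  expect_equal(near(g_bc, 12), near(g_bc, 48), tolerance = 0.15)
  # raw power inflates the slower tone markedly
  expect_gt(near(g_raw, 48) / near(g_raw, 12), 2)
})

test_that("corrected power is homogeneous of degree two", {
  set.seed(22)
  v <- rnorm(128)
  w1 <- cwt_morlet(regular_series(0, 1, v))
  w3 <- cwt_morlet(regular_series(0, 1, 3 * v))
  expect_equal(w3$power_bc, 9 * w1$power_bc, tolerance = 1e-10)
})

test_that("CWT is linear in its input", {
  set.seed(23)
  a <- rnorm(128); b <- rnorm(128)
  wa <- cwt_morlet(a, dt_h = 1); wb <- cwt_morlet(b, dt_h = 1)
  wab <- cwt_morlet(a + b, dt_h = 1)
  expect_equal(wab$coef, wa$coef + wb$coef, tolerance = 1e-10)
})

test_that("AR1 fitting recovers persistence and rejects degenerate input", {
  set.seed(24)
  wn <- rnorm(2000)
  expect_lt(abs(fit_ar1(wn)$ar1), 2 / sqrt(2000))
  x <- ar1_surrogate(5000, list(ar1 = 0.7, variance = 1))
  expect_equal(fit_ar1(x)$ar1, 0.7, tolerance = 0.05)
  expect_equal(fit_ar1(x)$variance, 1, tolerance = 0.15)
  expect_error(fit_ar1(rep(2, 100)), "constant")
  expect_error(fit_ar1(1:5), "at least 10")
})

test_that("chi-squared thresholds flag strong tones but not the null", {
  set.seed(25)
  n <- 512
  noise <- ar1_surrogate(n, list(ar1 = 0.5, variance = 0.04))
  tone <- sin(2 * pi * (0:(n - 1)) / 24)
  s <- regular_series(0, 1, tone + noise)
  w <- cwt_morlet(s)
  sig <- power_significance(w, fit_ar1(s$value))
  j24 <- which.min(abs(w$period - 24))
  inside24 <- w$coi_period_h > 24
  expect_gt(mean(sig$mask[j24, inside24]), 0.8)

  # degenerate level: everything is significant
  sig0 <- power_significance(w, fit_ar1(s$value), level = 0)
  expect_true(all(sig0$mask))
  expect_error(power_significance(w, level = 1.2), "level")
})

test_that("wavelets localize a transient oscillation in time", {
  set.seed(26)
  n <- 512
  x <- rnorm(n, sd = 0.2)
  x[(n / 2 + 1):n] <- x[(n / 2 + 1):n] + sin(2 * pi * (1:(n / 2)) / 24)
  s <- regular_series(0, 1, x)
  w <- cwt_morlet(s)
  sig <- power_significance(w, fit_ar1(x))
  j24 <- which.min(abs(w$period - 24))
  inside <- w$coi_period_h > 24
  first <- seq_len(n) <= n / 2 - 48
  second <- seq_len(n) > n / 2 + 48
  expect_gt(mean(sig$mask[j24, inside & second]), 0.8)
  expect_lt(mean(sig$mask[j24, inside & first]), 0.2)
})

test_that("two tones give two local maxima; empty input gives empty spectrum", {
  n <- 2048; t <- 0:(n - 1)
  s <- regular_series(0, 1, sin(2 * pi * t / 12) + sin(2 * pi * t / 24))
  g <- global_spectrum(cwt_morlet(s))
  j12 <- which.min(abs(g$period - 12)); j24 <- which.min(abs(g$period - 24))
  # both tone bins beat the trough between them
  trough <- which.min(abs(g$period - 17))
  expect_gt(g$power[j12], g$power[trough])
  expect_gt(g$power[j24], g$power[trough])

  z <- global_spectrum(cwt_morlet(regular_series(0, 1, rep(0, 64))))
  expect_true(all(z$power < 1e-20))
})
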