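# Bracketed interpolation, hourly grids, pairing, daily averages and
# correlations.

test_that("interpolation is exact at measurements and linear between them", {
  s <- irregular_series(c(0, 2), c(1, 3))
  expect_equal(interpolate_to(s, 1), 2)
  expect_identical(interpolate_to(s, 0), 1)
  expect_identical(interpolate_to(s, 2), 3)
  expect_true(is.na(interpolate_to(s, 2.5)))   # no upper bracket
  expect_true(is.na(interpolate_to(s, -1)))
  expect_error(interpolate_to(irregular_series(1, NA), 1), "no defined")
})

test_that("interpolation matches a brute-force bracket search on random series", {
  set.seed(14)
  brute <- function(t, f, tg) {
    le <- suppressWarnings(max(t[t <= tg]))
    ge <- suppressWarnings(min(t[t >= tg]))
    if (!is.finite(le) || !is.finite(ge)) return(NA_real_)
    if (le == ge) return(f[match(le, t)])
    fle <- f[match(le, t)]; fge <- f[match(ge, t)]
    (fge - fle) / (ge - le) * (tg - le) + fle
  }
  for (rep in 1:40) {
    n <- sample(5:40, 1)
    t <- sort(runif(n, 0, 100)); t <- t[!duplicated(t)]
    f <- rnorm(length(t))
    s <- irregular_series(t, f)
    targets <- c(runif(20, -5, 105), sample(t, min(5, length(t))))
    got <- interpolate_to(s, targets)
    want <- vapply(targets, function(tg) brute(t, f, tg), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("interpolation never extrapolates beyond the bracketing pair", {
  set.seed(15)
  t <- sort(runif(30, 0, 50)); f <- rnorm(30)
  s <- irregular_series(t, f)
  tg <- runif(200, 0, 50)
  v <- interpolate_to(s, tg)
  for (i in seq_along(tg)) {
    if (is.na(v[i])) next
    le <- max(t[t <= tg[i]]); ge <- min(t[t >= tg[i]])
    lo <- min(f[match(c(le, ge), t)]); hi <- max(f[match(c(le, ge), t)])
    expect_gte(v[i], lo - 1e-12); expect_lte(v[i], hi + 1e-12)
  }
})

test_that("hourly resampling preserves exact grids and guards long gaps", {
  s <- irregular_series(0:10, sin(0:10))
  h <- to_hourly(s)
  expect_s3_class(h, "regular_series")
  expect_equal(h$value, sin(0:10))

  # 10-minute series: hourly subsample equals direct interpolation
  t10 <- seq(0, 12, by = 1 / 6)
  s10 <- irregular_series(t10, cos(t10))
  h10 <- to_hourly(s10)
  expect_equal(h10$value, interpolate_to(s10, 0:12), tolerance = 1e-12)

  # a 3-day outage with a 24 h guard: in-gap grid points are missing
  tg <- c(0:10, 10 + 72 + 0:10)
  sg <- irregular_series(tg, rnorm(length(tg)))
  hg <- to_hourly(sg, max_gap_h = 24)
  tt <- series_times(hg)
  expect_true(all(is.na(hg$value[tt > 10 & tt < 82])))
  expect_true(all(!is.na(hg$value[tt <= 10 | tt >= 82])))
})

test_that("pairing maps the sensor onto the image time grid", {
  img <- irregular_series(c(1, 2, 3, 4), c(10, 20, 30, 40))
  sens <- irregular_series(c(1, 2, 3, 4), c(5, 6, 7, 8))
  pr <- pair_series(img, sens)
  expect_equal(pr$x, c(10, 20, 30, 40))
  expect_equal(pr$y, c(5, 6, 7, 8))
  expect_equal(attr(pr, "n_dropped"), 0)

  # sensor offset by 30 min on a linear signal: interpolated exactly
  sens2 <- irregular_series(c(0.5, 1.5, 2.5, 3.5, 4.5),
                            2 * c(0.5, 1.5, 2.5, 3.5, 4.5))
  pr2 <- pair_series(img, sens2)
  expect_equal(pr2$y, 2 * c(1, 2, 3, 4), tolerance = 1e-12)

  expect_error(pair_series(img, irregular_series(100:104, rnorm(5))),
               "overlap")
})

test_that("daily averages ignore empty days and never interpolate", {
  s <- irregular_series(0:23 + 0.5, rep(5, 24))
  da <- daily_average(s)
  expect_equal(nrow(da), 1)
  expect_equal(da$value, 5)

  # day 0 has 3 measurements, day 1 none, day 2 has 2
  s2 <- irregular_series(c(1, 5, 9, 49, 53), c(1, 2, 3, 10, 20))
  da2 <- daily_average(s2)
  expect_equal(da2$day, c(0, 2))
  expect_equal(da2$value, c(2, 15))
  expect_equal(da2$n, c(3L, 2L))
})

test_that("correlations use complete pairs and report n", {
  x <- 1:10
  expect_equal(series_correlation(x, 2 * x + 1, "pearson")$r, 1)
  r3 <- series_correlation(x, x^3, "spearman")
  expect_equal(r3$r, 1)
  expect_lt(series_correlation(x, x^3, "pearson")$r, 1)

  # worked pairs: hand-computed Pearson r = 0.6
  got <- series_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3), "pearson")
  expect_equal(got$r, 0.6, tolerance = 1e-12)
  expect_equal(got$n, 4)

  # incomplete pairs are dropped, not imputed
  xx <- c(1, 2, NA, 4, 5); yy <- c(2, 4, 6, NA, 10)
  expect_equal(series_correlation(xx, yy)$n, 3)

  expect_error(series_correlation(rep(1, 5), 1:5), "constant")
  expect_error(series_correlation(1:2, 1:2), "at least 3")

  # property: output always within [-1, 1]
  set.seed(16)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    expect_lte(abs(series_correlation(a, b)$r), 1)
    expect_lte(abs(series_correlation(a, b, "spearman")$r), 1)
  }
})
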