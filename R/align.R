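# Mapping irregular, gappy series onto common time grids.
#
# The interpolation rule is deliberately literal: for a target time t, take
# the latest defined measurement at or before t and the earliest at or after
# t, and interpolate linearly between them.  A target outside the measured
# span, or one whose bracketing pair straddles a gap longer than `max_gap_h`,
# is returned as missing rather than extrapolated.

#' Bracketed linear interpolation at arbitrary target times
#'
#' For each target `t` the value is
#' `f(t_le) + (f(t_ge) - f(t_le)) / (t_ge - t_le) * (t - t_le)` where `t_le`
#' is the latest measurement time `<= t` and `t_ge` the earliest `>= t`.
#' When `t` coincides with a measurement the stored value is returned
#' exactly (no arithmetic).  Targets without both brackets give `NA`.
#'
#' @param series an [irregular_series()] (or [regular_series()]).
#' @param targets target times (numeric hours or POSIXct).
#' @param max_gap_h optional guard: if the bracketing pair is more than this
#'   many hours apart the interpolated value is set to `NA` instead of
#'   silently bridging a long outage.  `Inf` (default) disables the guard.
#' @return numeric vector of interpolated values, `NA` where undefined.
#' @export
interpolate_to <- function(series, targets, max_gap_h = Inf) {
  p <- series_points(series)
  t <- p$time_h; f <- p$value
  tg <- time_to_hours(targets)
  out <- rep(NA_real_, length(tg))
  if (length(t) == 0L) rp_stop("empty series")
  # index of t_le for each target; 0 means no measurement <= target
  ile <- findInterval(tg, t)
  exact <- ile >= 1L & tg == t[pmax(ile, 1L)]
  out[exact] <- f[ile[exact]]
  todo <- !exact & ile >= 1L & ile < length(t)
  if (any(todo)) {
    i0 <- ile[todo]; i1 <- i0 + 1L
    dt <- t[i1] - t[i0]
    val <- f[i0] + (f[i1] - f[i0]) / dt * (tg[todo] - t[i0])
    val[dt > max_gap_h] <- NA_real_
    out[todo] <- val
  }
  out
}

#' Resample a series onto an equidistant grid
#'
#' Builds a grid from the first to the last defined measurement with step
#' `step_h` (1 hour by default, matching the imaging cadence) and fills it
#' with [interpolate_to()].  Grid points bridging gaps longer than
#' `max_gap_h` are marked missing.
#'
#' @inheritParams interpolate_to
#' @param step_h grid step in hours.
#' @return a [regular_series()].
#' @export
to_hourly <- function(series, step_h = 1, max_gap_h = Inf) {
  p <- series_points(series)
  if (length(p$time_h) == 0L) rp_stop("empty series")
  grid <- seq(p$time_h[1L], p$time_h[length(p$time_h)], by = step_h)
  v <- interpolate_to(series, grid, max_gap_h = max_gap_h)
  rs <- regular_series(grid[1L], step_h, v,
                       unit = series$unit, name = series$name)
  rs$posix <- p$posix
  rs
}

#' Pair an image-derived series with a sensor series
#'
#' Interpolates the sensor series at exactly the defined time points of the
#' image-derived series (the image cadence is the analysis grid; the sensor
#' is mapped onto it).  Pairs where the sensor value cannot be interpolated
#' are dropped and counted.
#'
#' @param image_series series whose time points define the pairing grid.
#' @param sensor_series series to be interpolated onto those time points.
#' @param max_gap_h gap guard passed to [interpolate_to()].
#' @return data.frame with columns `time_h`, `x` (image series value),
#'   `y` (interpolated sensor value); attribute `n_dropped` counts removed
#'   incomplete pairs.
#' @export
pair_series <- function(image_series, sensor_series, max_gap_h = Inf) {
  pi_ <- series_points(image_series)
  ps <- series_points(sensor_series)
  if (max(pi_$time_h) < min(ps$time_h) || min(pi_$time_h) > max(ps$time_h))
    rp_stop("series do not overlap in time")
  y <- interpolate_to(sensor_series, pi_$time_h, max_gap_h = max_gap_h)
  ok <- !is.na(y) & !is.na(pi_$value)
  out <- data.frame(time_h = pi_$time_h[ok], x = pi_$value[ok], y = y[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Daily averages of raw measurements
#'
#' Calendar-day (UTC) means of the available raw measurements.  No
#' interpolation is applied and days without any measurement are absent from
#' the output rather than zero-filled.
#'
#' @param series an [irregular_series()] or [regular_series()].
#' @return data.frame with columns `day` (integer days since epoch, UTC),
#'   `time_h` (midpoint of the day, hours), `value` (day mean), and `n`
#'   (number of contributing measurements).
#' @export
daily_average <- function(series) {
  p <- series_points(series)
  if (length(p$time_h) == 0L)
    return(data.frame(day = integer(), time_h = numeric(),
                      value = numeric(), n = integer()))
  day <- floor(p$time_h / 24)
  agg <- aggregate(p$value, by = list(day = day), FUN = mean)
  cnt <- as.integer(table(factor(day, levels = agg$day)))
  data.frame(day = agg$day, time_h = agg$day * 24 + 12,
             value = agg$x, n = cnt)
}

#' Pairwise correlation over complete pairs
#'
#' Pearson or Spearman correlation computed on complete pairs only (no
#' imputation), with the pair count reported alongside.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r` (coefficient), `n` (complete pairs used),
#'   `p_value`, and `method`.  A constant input yields an
#'   undefined-correlation error.
#' @export
series_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) rp_stop("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) rp_stop("need at least 3 complete pairs, have %d", length(x))
  if (sd(x) == 0 || sd(y) == 0)
    rp_stop("correlation undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), n = length(x), p_value = ct$p.value,
       method = method)
}
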