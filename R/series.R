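# Time-series containers used across the package.
#
# Internally all times are numeric hours.  POSIXct input is converted to
# hours since the Unix epoch (UTC), so "calendar day" arithmetic is plain
# integer division by 24.  The `posix` flag remembers how to format times
# on output.

#' Convert timestamps to numeric hours
#'
#' POSIXct (or anything `as.POSIXct` accepts, interpreted as UTC) becomes
#' hours since the Unix epoch; numeric input is returned unchanged and read
#' as hours.
#'
#' @param t numeric vector of hours, or POSIXct/character timestamps.
#' @return numeric vector of hours.
#' @export
time_to_hours <- function(t) {
  if (inherits(t, "POSIXt")) return(as.numeric(as.POSIXct(t, tz = "UTC")) / 3600)
  if (is.character(t)) return(as.numeric(as.POSIXct(t, tz = "UTC")) / 3600)
  if (inherits(t, "Date")) return(as.numeric(t) * 24)
  if (is.numeric(t)) return(as.numeric(t))
  rp_stop("unsupported timestamp type: %s", paste(class(t), collapse = "/"))
}

hours_to_posix <- function(h) as.POSIXct(h * 3600, origin = "1970-01-01", tz = "UTC")

#' Irregular measurement series
#'
#' A sensor or image-derived series sampled at its native, possibly
#' irregular and gappy, time points.  The stored timestamps are exactly the
#' set of defined measurements; a gap is simply an interval with no stored
#' timestamp.
#'
#' @param time timestamps (numeric hours or POSIXct); must be strictly
#'   increasing.
#' @param value numeric measurements, same length as `time`; `NA` entries are
#'   dropped (they mark failed measurements, i.e. gaps).
#' @param unit optional unit string (e.g. `"degC"`).
#' @param name optional source name (e.g. `"temperature"`).
#' @return an object of class `irregular_series` with fields `time_h`,
#'   `value`, `unit`, `name`, `posix`.
#' @export
irregular_series <- function(time, value, unit = NULL, name = NULL) {
  posix <- inherits(time, "POSIXt") || is.character(time) || inherits(time, "Date")
  th <- time_to_hours(time)
  if (length(th) != length(value)) rp_stop("time and value lengths differ")
  keep <- !is.na(th) & !is.na(value)
  th <- th[keep]; value <- as.numeric(value)[keep]
  if (length(th) == 0L) rp_stop("series has no defined measurements")
  if (any(diff(th) <= 0)) rp_stop("timestamps must be strictly increasing")
  structure(list(time_h = th, value = value, unit = unit, name = name,
                 posix = posix),
            class = "irregular_series")
}

#' @export
print.irregular_series <- function(x, ...) {
  cat(sprintf("<irregular_series%s> n=%d, span %.1f h, unit=%s\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$value), diff(range(x$time_h)),
              if (is.null(x$unit)) "?" else x$unit))
  invisible(x)
}

#' Regular (equidistant) series with explicit missing values
#'
#' @param start_h start time in hours (or POSIXct).
#' @param step_h grid step in hours (> 0).
#' @param value numeric vector; `NA` marks a missing grid point.
#' @param unit,name as in [irregular_series()].
#' @return object of class `regular_series`.
#' @export
regular_series <- function(start_h, step_h, value, unit = NULL, name = NULL) {
  posix <- inherits(start_h, "POSIXt") || is.character(start_h)
  s <- time_to_hours(start_h)
  rp_num1(s, "start_h"); rp_num1(step_h, "step_h")
  if (step_h <= 0) rp_stop("step_h must be > 0")
  structure(list(start_h = s, step_h = step_h, value = as.numeric(value),
                 unit = unit, name = name, posix = posix),
            class = "regular_series")
}

#' @export
print.regular_series <- function(x, ...) {
  cat(sprintf("<regular_series%s> n=%d, step %.3g h, %d missing\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              length(x$value), x$step_h, sum(is.na(x$value))))
  invisible(x)
}

#' Grid times of a regular series
#' @param x a `regular_series`.
#' @return numeric vector of hours.
#' @export
series_times <- function(x) {
  stopifnot(inherits(x, "regular_series"))
  x$start_h + (seq_along(x$value) - 1L) * x$step_h
}

# Coerce either series type to (time_h, value) pairs of defined measurements.
series_points <- function(x) {
  if (inherits(x, "irregular_series")) {
    list(time_h = x$time_h, value = x$value, posix = isTRUE(x$posix))
  } else if (inherits(x, "regular_series")) {
    t <- series_times(x); ok <- !is.na(x$value)
    list(time_h = t[ok], value = x$value[ok], posix = isTRUE(x$posix))
  } else rp_stop("expected an irregular_series or regular_series")
}
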