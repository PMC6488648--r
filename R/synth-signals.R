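# Synthetic sensor signals and annotation sets with known ground truth.
#
# Sensor series emulate the structure of coastal oceanographic records:
# slow trend + periodic components (tidal 12.4 h, diel 24 h, lunar ~707 h)
# + AR1 ("red") noise, sampled at a fixed cadence with outage gaps.

#' Specification of a synthetic sensor signal
#'
#' @param components data.frame (or list coercible to one) with columns
#'   `period` (hours, > 0), `amplitude`, `phase` (radians); may have zero
#'   rows.
#' @param trend piecewise-linear trend anchors: data.frame with `time_h`,
#'   `value`; a single row gives a constant offset.  Default constant 0.
#' @param ar1 AR1 coefficient of the additive noise, in \[0, 1).
#' @param noise_sd stationary standard deviation of the noise (0 = none).
#' @param gaps list of `c(start_h, end_h)` intervals with no measurements.
#' @param sampling_interval_min sampling cadence in minutes.
#' @return object of class `signal_spec`.
#' @export
signal_spec <- function(components = data.frame(period = numeric(),
                                                amplitude = numeric(),
                                                phase = numeric()),
                        trend = data.frame(time_h = 0, value = 0),
                        ar1 = 0, noise_sd = 0, gaps = list(),
                        sampling_interval_min = 60) {
  components <- as.data.frame(components)
  if (nrow(components) && (!all(c("period", "amplitude") %in% names(components))))
    rp_stop("components needs columns period, amplitude (and optionally phase)")
  if (nrow(components) && is.null(components$phase)) components$phase <- 0
  if (nrow(components) && any(components$period <= 0))
    rp_stop("component periods must be > 0")
  rp_num1(ar1, "ar1"); rp_num1(noise_sd, "noise_sd")
  if (ar1 < 0 || ar1 >= 1) rp_stop("ar1 must be in [0, 1)")
  if (sampling_interval_min <= 0) rp_stop("sampling interval must be > 0")
  trend <- as.data.frame(trend)
  if (!all(c("time_h", "value") %in% names(trend)))
    rp_stop("trend needs columns time_h, value")
  structure(list(components = components, trend = trend, ar1 = ar1,
                 noise_sd = noise_sd, gaps = gaps,
                 sampling_interval_min = sampling_interval_min),
            class = "signal_spec")
}

# Evaluate the deterministic part (trend + periodic components) at times t.
signal_truth <- function(spec, t_h) {
  tr <- spec$trend
  v <- if (nrow(tr) == 1L) rep(tr$value, length(t_h)) else
    approx(tr$time_h, tr$value, xout = t_h, rule = 2)$y
  if (nrow(spec$components)) {
    for (i in seq_len(nrow(spec$components))) {
      cc <- spec$components[i, ]
      v <- v + cc$amplitude * sin(2 * pi * t_h / cc$period + cc$phase)
    }
  }
  v
}

#' Generate an irregular synthetic sensor series
#'
#' Values are trend + sum of sinusoids + stationary AR1 noise, sampled at
#' the spec's cadence over `n_hours`; measurements falling inside a gap
#' interval are removed (not blanked), as in an instrument outage.
#'
#' @param spec a [signal_spec()].
#' @param n_hours record length in hours.
#' @param seed RNG seed (fixed seed gives an identical series).
#' @param name,unit passed to the returned series.
#' @return an [irregular_series()]; the noise-free truth is attached as
#'   attribute `"truth"`.
#' @export
generate_sensor_series <- function(spec, n_hours, seed = 1,
                                   name = NULL, unit = NULL) {
  stopifnot(inherits(spec, "signal_spec"))
  if (n_hours <= 0) rp_stop("n_hours must be > 0")
  step <- spec$sampling_interval_min / 60
  t_h <- seq(0, n_hours, by = step)
  truth <- signal_truth(spec, t_h)
  v <- truth
  if (spec$noise_sd > 0) {
    set.seed(seed)
    v <- v + ar1_surrogate(length(t_h),
                           list(ar1 = spec$ar1, variance = spec$noise_sd^2))
  }
  keep <- rep(TRUE, length(t_h))
  for (g in spec$gaps) {
    if (g[2] < g[1]) rp_stop("gap interval reversed")
    keep <- keep & !(t_h >= g[1] & t_h <= g[2])
  }
  if (!any(keep)) rp_stop("gaps remove every measurement")
  out <- irregular_series(t_h[keep], v[keep], unit = unit, name = name)
  attr(out, "truth") <- truth[keep]
  out
}

#' Simulate point annotations of polyp states
#'
#' One point annotation per true polyp, with the marked position perturbed
#' by isotropic Gaussian error and the state label flipped with a fixed
#' probability, emulating imperfect human annotators.
#'
#' @param truths a single `scene_truth` or list of them (see
#'   [scene_truth()]); each contributes annotations for its frame.
#' @param annotator_error_rate label-flip probability in \[0, 0.5).
#' @param position_sd positional jitter sd in pixels.
#' @param annotator annotator id attached to the records.
#' @param seed RNG seed.
#' @return data.frame (`annotation_set`) with columns `image` (frame index
#'   or id), `x`, `y`, `class` (`"active"`/`"inactive"`), `annotator`.
#' @export
generate_annotations <- function(truths, annotator_error_rate = 0,
                                 position_sd = 0, annotator = "A1",
                                 seed = 1) {
  if (inherits(truths, "scene_truth")) truths <- list(truths)
  if (annotator_error_rate < 0 || annotator_error_rate >= 0.5)
    rp_stop("annotator_error_rate must be in [0, 0.5)")
  set.seed(seed)
  rows <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    pc <- tr$polyp_centres
    if (nrow(pc) == 0L) next
    x <- pc$x + rnorm(nrow(pc), sd = position_sd)
    y <- pc$y + rnorm(nrow(pc), sd = position_sd)
    flip <- runif(nrow(pc)) < annotator_error_rate
    state <- ifelse(xor(pc$state == "active", flip), "active", "inactive")
    id <- if (!is.null(tr$id)) tr$id else i
    rows[[length(rows) + 1L]] <-
      data.frame(image = id, x = x, y = y, class = state,
                 annotator = annotator)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(image = integer(), x = numeric(), y = numeric(),
               class = character(), annotator = character())
  class(out) <- c("annotation_set", class(out))
  out
}
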