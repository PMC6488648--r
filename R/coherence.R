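# Wavelet coherence between two series on the same grid.
#
# Squared coherence R^2 = |S(W_xy / s)|^2 / (S(|W_x|^2 / s) S(|W_y|^2 / s))
# with a smoothing operator S that is Gaussian in time (envelope width
# proportional to scale) followed by a boxcar across scales (0.6 octave).
# Without smoothing the ratio is identically 1; the smoothing windows set
# the effective number of degrees of freedom.  Phase is the argument of the
# smoothed cross-spectrum: 0 = in phase (arrows right), +/-pi =
# counter-phase, +pi/2 = y lags x by a quarter period.

# Smooth each scale row in time with a Gaussian of sd = scale/dt samples
# (FFT convolution, truncated at the record ends by renormalization).
smooth_time_gauss <- function(M, scale, dt) {
  n <- ncol(M)
  npad <- 2^ceiling(log2(2 * n))
  out <- M
  ones <- c(rep(1, n), rep(0, npad - n))
  Fones <- fft(ones)
  for (j in seq_len(nrow(M))) {
    sdj <- scale[j] / dt
    half <- npad / 2
    tt <- c(0:(half - 1), -(half:1))
    g <- exp(-0.5 * (tt / sdj)^2)
    g <- g / sum(g)
    Fg <- fft(g)
    row <- c(M[j, ], rep(0, npad - n))
    sm <- fft(fft(row) * Fg, inverse = TRUE) / npad
    w <- Re(fft(Fones * Fg, inverse = TRUE)) / npad  # local window mass
    out[j, ] <- sm[seq_len(n)] / w[seq_len(n)]
  }
  out
}

# Boxcar smoothing across scales spanning ~`octaves` octaves (window of
# round(octaves/dj) points, truncated and renormalized at the ladder ends).
smooth_scale_boxcar <- function(M, dj, octaves = 0.6) {
  win <- max(1L, round(octaves / dj))
  if (win <= 1L) return(M)
  half <- floor(win / 2)
  ns <- nrow(M)
  out <- M
  for (j in seq_len(ns)) {
    idx <- max(1L, j - half):min(ns, j + half)
    out[j, ] <- colMeans(M[idx, , drop = FALSE])
  }
  out
}

#' Squared wavelet coherence and phase between two series
#'
#' @param x,y [regular_series()] on identical grids (same start, step and
#'   length), gapless.
#' @param dj scale resolution in octaves (default 1/12).
#' @param max_period_h largest analysed period (default spans the record).
#' @param omega0 Morlet parameter.
#' @param scale_octaves width of the boxcar scale smoothing in octaves.
#' @return object of class `wavelet_coherence`: `time_h`, `scale`, `period`,
#'   `r2` (squared coherence in \[0, 1\]), `phase` (radians in (-pi, pi\]),
#'   `coi_period_h`, the two fitted `noise_model`s, and the smoothing
#'   parameters.
#' @export
wavelet_coherence <- function(x, y, dj = 1 / 12, max_period_h = NULL,
                              omega0 = 6, scale_octaves = 0.6) {
  stopifnot(inherits(x, "regular_series"), inherits(y, "regular_series"))
  if (length(x$value) != length(y$value) || x$step_h != y$step_h ||
      x$start_h != y$start_h)
    rp_stop("coherence requires identical time grids")
  wx <- cwt_morlet(x, dj = dj, max_period_h = max_period_h, omega0 = omega0)
  wy <- cwt_morlet(y, dj = dj, max_period_h = max_period_h, omega0 = omega0)
  sc <- wx$scale; dt <- wx$dt
  inv_s <- 1 / sc
  Wxy <- (wx$coef * Conj(wy$coef)) * inv_s
  Sxx <- smooth_scale_boxcar(
    smooth_time_gauss(wx$power * inv_s, sc, dt), dj, scale_octaves)
  Syy <- smooth_scale_boxcar(
    smooth_time_gauss(wy$power * inv_s, sc, dt), dj, scale_octaves)
  Sxy <- smooth_scale_boxcar(
    smooth_time_gauss(Wxy, sc, dt), dj, scale_octaves)
  r2 <- Mod(Sxy)^2 / (Re(Sxx) * Re(Syy))
  r2 <- pmin(pmax(r2, 0), 1)
  dim(r2) <- dim(wx$power)
  structure(list(time_h = wx$time_h, scale = sc, period = wx$period,
                 r2 = r2, phase = Arg(Sxy), coi_period_h = wx$coi_period_h,
                 dt = dt, dj = dj, omega0 = omega0,
                 scale_octaves = scale_octaves,
                 noise_x = tryCatch(fit_ar1(x), error = function(e) NULL),
                 noise_y = tryCatch(fit_ar1(y), error = function(e) NULL),
                 max_period_h = max_period_h),
            class = "wavelet_coherence")
}

#' @export
print.wavelet_coherence <- function(x, ...) {
  cat(sprintf("<wavelet_coherence> %d times x %d scales, periods %.2f-%.1f h\n",
              length(x$time_h), length(x$scale), min(x$period), max(x$period)))
  invisible(x)
}

#' Monte Carlo significance of wavelet coherence
#'
#' Per-scale coherence thresholds from AR1 (red-noise) surrogate pairs
#' matched to the two observed series' lag-1 autocorrelation and variance:
#' the observed coherence is significant where it exceeds the level-quantile
#' of the surrogate coherence values (pooled over inside-COI times) at the
#' same scale.
#'
#' @param coh a `wavelet_coherence` of the observed pair.
#' @param n_surrogates number of surrogate pairs (>= 100).
#' @param seed RNG seed for the surrogate draws.
#' @param level significance level (default 0.95).
#' @return list with `mask` (TRUE = significant), `threshold` (per-scale),
#'   `level`, `n_surrogates`.
#' @export
coherence_significance <- function(coh, n_surrogates = 300, seed = 1,
                                   level = 0.95) {
  stopifnot(inherits(coh, "wavelet_coherence"))
  if (n_surrogates < 100) rp_stop("n_surrogates must be >= 100")
  if (is.null(coh$noise_x) || is.null(coh$noise_y))
    rp_stop("series too short to fit the AR1 null models")
  n <- length(coh$time_h)
  inside <- outer(coh$period, coh$coi_period_h, `<`)
  ns <- length(coh$scale)
  acc <- vector("list", ns)
  set.seed(seed)
  gx <- regular_series(0, coh$dt, numeric(n))
  gy <- gx
  for (b in seq_len(n_surrogates)) {
    gx$value <- ar1_surrogate(n, coh$noise_x)
    gy$value <- ar1_surrogate(n, coh$noise_y)
    cb <- wavelet_coherence(gx, gy, dj = coh$dj,
                            max_period_h = coh$max_period_h,
                            omega0 = coh$omega0,
                            scale_octaves = coh$scale_octaves)
    for (j in seq_len(ns)) {
      v <- cb$r2[j, inside[j, ]]
      if (length(v)) acc[[j]] <- c(acc[[j]], v)
    }
  }
  thr <- vapply(acc, function(v)
    if (length(v)) unname(quantile(v, level)) else NA_real_, numeric(1))
  mask <- coh$r2 > matrix(thr, nrow = ns, ncol = n)
  mask[is.na(mask)] <- FALSE
  list(mask = mask, threshold = thr, level = level,
       n_surrogates = n_surrogates)
}

#' Scale-averaged coherence curve
#'
#' Time-mean squared coherence per scale, restricted to inside-COI points.
#'
#' @param coh a `wavelet_coherence`.
#' @param period_band optional `c(min, max)` period window in hours.
#' @return data.frame with `scale`, `period`, `coherence`, `n`.
#' @export
scale_averaged_coherence <- function(coh, period_band = NULL) {
  stopifnot(inherits(coh, "wavelet_coherence"))
  keep <- rep(TRUE, length(coh$period))
  if (!is.null(period_band))
    keep <- coh$period >= period_band[1] & coh$period <= period_band[2]
  if (!any(keep)) rp_stop("empty period band")
  inside <- outer(coh$period, coh$coi_period_h, `<`)
  r2 <- coh$r2; r2[!inside] <- NA_real_
  m <- rowMeans(r2, na.rm = TRUE)
  n <- rowSums(inside)
  m[n == 0] <- NA_real_
  data.frame(scale = coh$scale[keep], period = coh$period[keep],
             coherence = m[keep], n = n[keep])
}
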