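# Scalogram-style plotting helpers (heat map + significance contour +
# COI shading; phase arrows for coherence).

# Shared scaffold: draw a scale x time grid as an image with log2 period
# axis, overlay a significance contour and shade outside the COI.
plot_scalogram <- function(time_h, period, grid, coi, signif_mask = NULL,
                           main = "", col = grDevices::hcl.colors(64, "viridis"),
                           zlim = NULL) {
  lp <- log2(period)
  graphics::image(time_h, lp, t(grid), col = col, zlim = zlim,
                  xlab = "time [h]", ylab = "period [h]", yaxt = "n",
                  main = main, useRaster = TRUE)
  at <- pretty(lp)
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  if (!is.null(signif_mask) && any(signif_mask))
    graphics::contour(time_h, lp, t(signif_mask * 1), levels = 0.5,
                      add = TRUE, drawlabels = FALSE, lwd = 1.5)
  graphics::lines(time_h, log2(pmax(coi, min(period))), lty = 2)
  pc <- pmax(pmin(coi, max(period)), min(period))
  graphics::polygon(c(time_h, rev(time_h)),
                    c(log2(pc), rep(log2(max(period)), length(time_h))),
                    col = grDevices::adjustcolor("white", 0.35), border = NA)
}

#' Plot a wavelet power spectrum with its global spectrum
#'
#' Two panels in the style of observatory time-series analyses: the
#' bias-corrected power scalogram with significance contour and COI
#' shading, and the scale-averaged global spectrum with optional
#' reference periods (tidal 12.4 h, diel 24 h, lunar ~707 h).
#'
#' @param spectrum a [cwt_morlet()] result.
#' @param significance optional [power_significance()] result.
#' @param reference_periods_h periods marked in the global panel.
#' @param main plot title.
#' @export
plot_wavelet_power <- function(spectrum, significance = NULL,
                               reference_periods_h = c(12.4, 24, 707),
                               main = spectrum$name %||% "") {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot_scalogram(spectrum$time_h, spectrum$period,
                 log1p(spectrum$power_bc), spectrum$coi_period_h,
                 if (!is.null(significance)) significance$mask else NULL,
                 main = main)
  gs <- global_spectrum(spectrum)
  graphics::plot(gs$power, log2(gs$period), type = "l", yaxt = "n",
                 xlab = "global power", ylab = "period [h]",
                 main = "global spectrum")
  at <- pretty(log2(gs$period))
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  rp <- reference_periods_h[reference_periods_h <= max(gs$period) &
                              reference_periods_h >= min(gs$period)]
  graphics::abline(h = log2(rp), lty = 3, col = "grey40")
  invisible(NULL)
}

#' Plot squared wavelet coherence with phase arrows
#'
#' Heat map of squared coherence with significance contour, COI shading
#' and phase arrows (right = in phase, left = counter-phase), plus the
#' scale-averaged coherence panel.
#'
#' @param coh a [wavelet_coherence()] result.
#' @param significance optional [coherence_significance()] result.
#' @param arrow_every subsampling step (time and scale) for phase arrows.
#' @param main plot title.
#' @export
plot_wavelet_coherence <- function(coh, significance = NULL,
                                   arrow_every = c(24, 6), main = "") {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot_scalogram(coh$time_h, coh$period, coh$r2, coh$coi_period_h,
                 if (!is.null(significance)) significance$mask else NULL,
                 main = main, zlim = c(0, 1))
  ti <- seq(1L, length(coh$time_h), by = arrow_every[1])
  si <- seq(1L, length(coh$period), by = arrow_every[2])
  dt_plot <- diff(range(coh$time_h)) / 40
  dp_plot <- diff(range(log2(coh$period))) / 40
  for (j in si) for (i in ti) {
    if (coh$period[j] >= coh$coi_period_h[i]) next
    ph <- coh$phase[j, i]
    graphics::arrows(coh$time_h[i], log2(coh$period[j]),
                     coh$time_h[i] + dt_plot * cos(ph),
                     log2(coh$period[j]) + dp_plot * sin(ph),
                     length = 0.03, col = "black")
  }
  sac <- scale_averaged_coherence(coh)
  graphics::plot(sac$coherence, log2(sac$period), type = "l", xlim = c(0, 1),
                 yaxt = "n", xlab = "scale-averaged coherence",
                 ylab = "period [h]", main = "")
  at <- pretty(log2(sac$period))
  graphics::axis(2, at = at, labels = signif(2^at, 3))
  invisible(NULL)
}
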