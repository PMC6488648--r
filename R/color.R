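# Colour operations: fixed white balance, CIELab conversion, region means.
#
# Colour convention: sRGB primaries with the D65 white point and the
# standard CIELab transform — the default interpretation of consumer
# camera output when no profile is given.

#' Apply fixed per-channel white-balance gains
#'
#' Each channel is scaled by its gain and clipped to \[0, 1\].  The gains
#' are meant to be estimated once (e.g. from a neutral reference patch in
#' the reference frame) and then held fixed over the whole sequence so
#' frame-to-frame colour differences are preserved.
#'
#' @param frame a [reef_frame()].
#' @param gains numeric length-3 vector of positive per-channel gains.
#' @return the rebalanced `reef_frame`.
#' @export
white_balance <- function(frame, gains = c(1, 1, 1)) {
  stopifnot(inherits(frame, "reef_frame"))
  if (length(gains) != 3L || any(!is.finite(gains)) || any(gains <= 0))
    rp_stop("gains must be 3 positive numbers")
  d <- frame$data
  for (c in 1:3) d[, , c] <- pmin(pmax(d[, , c] * gains[c], 0), 1)
  reef_frame(d, frame$timestamp, frame$valid)
}

#' Estimate white-balance gains from a neutral reference patch
#'
#' Gains that map the patch's mean RGB to a neutral grey of the same
#' overall luminance.
#'
#' @param frame a [reef_frame()].
#' @param patch `c(x0, y0, x1, y1)` pixel rectangle assumed neutral grey.
#' @return numeric length-3 gain vector.
#' @export
estimate_wb_gains <- function(frame, patch) {
  stopifnot(inherits(frame, "reef_frame"))
  p <- frame$data[patch[2]:patch[4], patch[1]:patch[3], , drop = FALSE]
  ch <- apply(p, 3, mean)
  if (any(ch <= 0)) rp_stop("reference patch has a zero channel")
  mean(ch) / ch
}

#' Convert an RGB frame to a CIELab raster
#'
#' Per-pixel sRGB (D65) to CIELab conversion.
#'
#' @param frame a [reef_frame()] or an RGB array in \[0, 1\].
#' @return numeric array `height x width x 3` with channels L, a, b.
#' @export
rgb_to_lab <- function(frame) {
  d <- if (inherits(frame, "reef_frame")) frame$data else frame
  dm <- dim(d)
  lab <- farver::convert_colour(matrix(d, ncol = 3L) * 255,
                                from = "rgb", to = "lab")
  array(lab, dm)
}

#' Convert a CIELab raster back to sRGB
#'
#' @param lab numeric array `height x width x 3` (L, a, b).
#' @return RGB array in \[0, 1\] (out-of-gamut values clipped).
#' @export
lab_to_rgb <- function(lab) {
  dm <- dim(lab)
  rgb <- farver::convert_colour(matrix(lab, ncol = 3L),
                                from = "lab", to = "rgb") / 255
  array(pmin(pmax(rgb, 0), 1), dm)
}

#' Mean CIELab colour over a pixel set
#'
#' Arithmetic mean of L, a, b over the masked pixels, or over all pixels
#' when no mask is given (the full-image mean and the masked mean coincide
#' when the mask covers everything).
#'
#' @param lab `height x width x 3` Lab raster.
#' @param mask optional logical matrix selecting pixels; must contain at
#'   least one `TRUE` pixel.
#' @return named numeric vector `c(L=, a=, b=)`; attribute `n_px` gives the
#'   pixel count averaged.
#' @export
mean_color <- function(lab, mask = NULL) {
  dm <- dim(lab)
  if (is.null(mask)) {
    v <- colMeans(matrix(lab, ncol = 3L))
    n <- dm[1] * dm[2]
  } else {
    if (!identical(dim(mask), dm[1:2]))
      rp_stop("mask dimensions do not match the raster")
    n <- sum(mask)
    if (n == 0L) rp_stop("empty mask: no pixels to average")
    v <- c(mean(lab[, , 1][mask]), mean(lab[, , 2][mask]),
           mean(lab[, , 3][mask]))
  }
  structure(setNames(v, c("L", "a", "b")), n_px = n)
}
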