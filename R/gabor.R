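# Gabor filter bank: oriented band-pass texture features.
#
# Filtering is circular FFT convolution.  The even/odd quadrature pair is
# folded into one complex kernel (even + i*odd), so one inverse FFT per
# filter yields the magnitude response.  Kernel spectra depend only on the
# image size and the bank, so they are cached across frames of a sequence.

#' Build a Gabor kernel
#'
#' Quadrature pair (even = cosine, odd = sine phase) of an oriented Gabor
#' filter.  The envelope sd defaults to `0.56 * wavelength` (about one
#' octave bandwidth).
#'
#' @param wavelength carrier wavelength in pixels.
#' @param orientation carrier orientation in radians (0 = horizontal wave
#'   vector, i.e. vertical stripes).
#' @param sigma Gaussian envelope sd in pixels.
#' @param gamma spatial aspect ratio of the envelope.
#' @return list with matrices `even` and `odd` (zero-mean even part, both
#'   unit-norm) and the kernel size `size`.
#' @export
gabor_kernel <- function(wavelength, orientation, sigma = 0.56 * wavelength,
                         gamma = 1) {
  half <- max(3L, ceiling(2.5 * sigma))
  g <- expand.grid(y = -half:half, x = -half:half)
  xp <- g$x * cos(orientation) + g$y * sin(orientation)
  yp <- -g$x * sin(orientation) + g$y * cos(orientation)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xp / wavelength)
  odd <- env * sin(2 * pi * xp / wavelength)
  n <- 2L * half + 1L
  even <- matrix(even, n, n); odd <- matrix(odd, n, n)
  even <- even - mean(even)           # zero DC so flat regions respond 0
  even <- even / sqrt(sum(even^2))
  odd <- odd / sqrt(sum(odd^2))
  list(even = even, odd = odd, size = n)
}

#' Default Gabor bank specification
#'
#' @param wavelengths carrier wavelengths in pixels.
#' @param n_orientations number of evenly spaced orientations in \[0, pi).
#' @param pool_orientations pool magnitude responses over orientation
#'   (rotation-robust features, one per wavelength).
#' @param smooth_sd Gaussian sd (pixels) for smoothing the magnitude
#'   responses into locally stable texture-energy features.
#' @return list of class `gabor_bank`.
#' @export
gabor_bank <- function(wavelengths = c(4, 8, 16, 32), n_orientations = 6,
                       pool_orientations = TRUE, smooth_sd = 4) {
  if (!length(wavelengths)) rp_stop("empty Gabor bank")
  structure(list(wavelengths = wavelengths,
                 orientations = seq(0, pi, length.out = n_orientations + 1L)[
                   seq_len(n_orientations)],
                 pool_orientations = pool_orientations,
                 smooth_sd = smooth_sd),
            class = "gabor_bank")
}

# Place a small kernel on an h x w canvas with its centre wrapped to
# (1, 1), matching circular FFT convolution alignment.
wrap_kernel <- function(k, h, w) {
  n <- nrow(k); half <- (n - 1L) %/% 2L
  if (n > h || n > w) rp_stop("kernel larger than image")
  K <- matrix(0, h, w)
  ri <- ((-half:half) %% h) + 1L
  ci <- ((-half:half) %% w) + 1L
  K[ri, ci] <- k
  K
}

# Per-image-size cache of kernel spectra.
.gabor_cache <- new.env(parent = emptyenv())

gabor_spectra <- function(bank, h, w) {
  key <- paste(h, w, paste(bank$wavelengths, collapse = ","),
               length(bank$orientations), bank$smooth_sd, sep = "|")
  hit <- .gabor_cache[[key]]
  if (!is.null(hit)) return(hit)
  specs <- list()
  for (i in seq_along(bank$wavelengths)) {
    for (j in seq_along(bank$orientations)) {
      k <- gabor_kernel(bank$wavelengths[i], bank$orientations[j])
      cplx <- wrap_kernel(k$even, h, w) + 1i * wrap_kernel(k$odd, h, w)
      specs[[paste(i, j)]] <- fft(cplx)
    }
  }
  smooth_f <- NULL
  if (bank$smooth_sd > 0) {
    half <- ceiling(3 * bank$smooth_sd)
    gx <- exp(-0.5 * ((-half:half) / bank$smooth_sd)^2)
    gk <- outer(gx, gx); gk <- gk / sum(gk)
    smooth_f <- fft(wrap_kernel(gk, h, w))
  }
  out <- list(specs = specs, smooth_f = smooth_f)
  .gabor_cache[[key]] <- out
  out
}

#' Per-pixel Gabor texture features
#'
#' Convolves the luminance channel with the quadrature bank, takes the
#' magnitude (texture energy) per wavelength/orientation, optionally pools
#' over orientations, and smooths the result into locally stable features.
#'
#' @param frame a [reef_frame()] or a numeric matrix (grayscale image).
#' @param bank a [gabor_bank()].
#' @return numeric array `height x width x d` with
#'   `d = length(wavelengths)` (pooled) or
#'   `length(wavelengths) * n_orientations`.
#' @export
extract_gabor_features <- function(frame, bank = gabor_bank()) {
  stopifnot(inherits(bank, "gabor_bank"))
  img <- if (inherits(frame, "reef_frame")) frame_gray(frame) else frame
  h <- nrow(img); w <- ncol(img)
  sp <- gabor_spectra(bank, h, w)
  Fimg <- fft(img)
  nw <- length(bank$wavelengths); no <- length(bank$orientations)
  d <- if (bank$pool_orientations) nw else nw * no
  out <- array(0, c(h, w, d))
  smooth_mat <- function(m) {
    if (is.null(sp$smooth_f)) return(m)
    Re(fft(fft(m) * sp$smooth_f, inverse = TRUE)) / (h * w)
  }
  for (i in seq_len(nw)) {
    pooled <- if (bank$pool_orientations) matrix(0, h, w) else NULL
    for (j in seq_len(no)) {
      resp <- fft(Fimg * sp$specs[[paste(i, j)]], inverse = TRUE) / (h * w)
      mag <- Mod(resp)
      if (bank$pool_orientations) {
        pooled <- pooled + mag / no
      } else {
        out[, , (i - 1L) * no + j] <- smooth_mat(mag)
      }
    }
    if (bank$pool_orientations) out[, , i] <- smooth_mat(pooled)
  }
  out
}

# Flatten a feature array to an n_pixels x d matrix (pixel order = R
# column-major over the image grid).
feature_matrix <- function(features) {
  d <- dim(features)
  matrix(features, nrow = d[1] * d[2], ncol = d[3])
}
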