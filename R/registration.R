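# Translation-only frame registration by phase correlation.
#
# The camera is fixed; residual motion is small whole-frame jitter, so a
# translation model against a fixed reference frame suffices.  The
# normalized cross-power spectrum of the two luminance channels has an
# impulse at the translation offset; its peak height is a quality score
# (near 1 for a clean translation, ~0 for unrelated content).

#' Estimate the translation between a frame and a reference
#'
#' @param frame,reference [reef_frame()]s (or grayscale matrices) of equal
#'   size.
#' @return list with `shift` (`c(dx, dy)` in pixels: the frame content is
#'   the reference content moved by `+shift`) and `quality` (phase
#'   correlation peak in \[0, 1\]).
#' @export
estimate_shift <- function(frame, reference) {
  g1 <- if (inherits(frame, "reef_frame")) frame_gray(frame) else frame
  g0 <- if (inherits(reference, "reef_frame")) frame_gray(reference) else reference
  if (!identical(dim(g1), dim(g0))) rp_stop("frames differ in size")
  g1 <- g1 - mean(g1); g0 <- g0 - mean(g0)
  if (sd(g1) == 0 || sd(g0) == 0)
    return(list(shift = c(NA_integer_, NA_integer_), quality = 0))
  F1 <- fft(g1); F0 <- fft(g0)
  cp <- F1 * Conj(F0)
  m <- Mod(cp); m[m < 1e-12] <- 1e-12
  r <- Re(fft(cp / m, inverse = TRUE)) / length(g1)
  peak <- which.max(r)
  pr <- (peak - 1L) %% nrow(r)          # 0-based row offset = dy
  pc <- (peak - 1L) %/% nrow(r)         # 0-based col offset = dx
  dy <- if (pr > nrow(r) / 2) pr - nrow(r) else pr
  dx <- if (pc > ncol(r) / 2) pc - ncol(r) else pc
  list(shift = c(dx = dx, dy = dy), quality = max(r))
}

# Integer-roll an image matrix (or each channel) by -shift so its content
# re-aligns with the reference; returns rolled data plus a validity mask
# that flags the wrapped border strips.
roll_back <- function(data, shift) {
  dx <- shift[1]; dy <- shift[2]
  h <- dim(data)[1]; w <- dim(data)[2]
  ri <- ((seq_len(h) - 1L + dy) %% h) + 1L
  ci <- ((seq_len(w) - 1L + dx) %% w) + 1L
  out <- data[ri, ci, , drop = FALSE]
  valid <- matrix(TRUE, h, w)
  if (dy > 0) valid[(h - dy + 1L):h, ] <- FALSE else if (dy < 0)
    valid[seq_len(-dy), ] <- FALSE
  if (dx > 0) valid[, (w - dx + 1L):w] <- FALSE else if (dx < 0)
    valid[, seq_len(-dx)] <- FALSE
  list(data = out, valid = valid)
}

#' Align a frame to a reference frame
#'
#' Estimates the translation by phase correlation and resamples the frame
#' (whole-pixel roll) so its content aligns with the reference.  Pixels
#' wrapped in from the opposite border are flagged invalid.  A correlation
#' peak below `min_quality` signals alignment failure — the frame should
#' then be excluded from downstream series.
#'
#' @param frame,reference [reef_frame()]s of equal size.
#' @param min_quality minimum acceptable phase-correlation peak.
#' @param max_shift largest plausible |shift| component in pixels; larger
#'   estimates are treated as failures.
#' @return list of class `registration`: `frame` (aligned `reef_frame`
#'   with validity mask; `NULL` on failure), `shift`, `quality`,
#'   `success`.
#' @export
register_frame <- function(frame, reference, min_quality = 0.05,
                           max_shift = 64) {
  est <- estimate_shift(frame, reference)
  ok <- est$quality >= min_quality && all(is.finite(est$shift)) &&
    all(abs(est$shift) <= max_shift)
  if (!ok)
    return(structure(list(frame = NULL, shift = est$shift,
                          quality = est$quality, success = FALSE),
                     class = "registration"))
  rb <- roll_back(frame$data, est$shift)
  valid <- rb$valid
  if (!is.null(frame$valid)) valid <- valid & frame$valid
  structure(list(frame = reef_frame(rb$data, frame$timestamp, valid = valid),
                 shift = est$shift, quality = est$quality, success = TRUE),
            class = "registration")
}
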