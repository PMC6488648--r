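# The coral colour time series: per frame, register -> fixed white balance
# -> CIELab -> live-coral segmentation -> masked mean; the series value
# xi_t is the a-channel (red-green axis) of the live-coral mean.  L and b
# are computed and stored as well so their (expected) flatness can be
# re-checked.

#' Compute the coral colour series from a frame sequence
#'
#' @param frames time-ordered list of [reef_frame()]s with timestamps.
#' @param labeller a trained [train_pixel_labeller()] for the live-coral
#'   segmentation.
#' @param gains fixed white-balance gains applied to every frame.
#' @param reference reference frame for registration (default: the first
#'   frame of the sequence).
#' @param register align each frame to the reference before measuring
#'   (disable only for pre-aligned input).
#' @param min_quality,max_shift registration failure thresholds, see
#'   [register_frame()].
#' @param clean_radius morphological clean-up radius for the mask.
#' @return a `color_series`: data.frame with one row per input frame —
#'   `time_h`, `xi_a` (the series value), `L`, `b`, `mask_area_px`,
#'   `shift_x`, `shift_y`, `status` (`"ok"` or a failure reason).  Failed
#'   frames keep their row with `NA` measurements, marking the gap.
#'   [as_series()] converts the `xi_a` column to an [irregular_series()].
#' @export
color_series <- function(frames, labeller, gains = c(1, 1, 1),
                         reference = NULL, register = TRUE,
                         min_quality = 0.05, max_shift = 64,
                         clean_radius = 2) {
  if (!length(frames)) rp_stop("no frames")
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (anyNA(ts)) rp_stop("all frames need timestamps")
  if (is.unsorted(ts, strictly = TRUE)) rp_stop("frames must be time-ordered")
  if (is.null(reference)) reference <- frames[[1L]]

  n <- length(frames)
  out <- data.frame(time_h = ts, xi_a = NA_real_, L = NA_real_, b = NA_real_,
                    mask_area_px = NA_integer_, shift_x = NA_integer_,
                    shift_y = NA_integer_, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (register) {
      reg <- register_frame(fr, reference, min_quality = min_quality,
                            max_shift = max_shift)
      if (!reg$success) { out$status[i] <- "alignment_failure"; next }
      fr <- reg$frame
      out$shift_x[i] <- reg$shift[1]; out$shift_y[i] <- reg$shift[2]
    } else {
      out$shift_x[i] <- 0L; out$shift_y[i] <- 0L
    }
    fr <- white_balance(fr, gains)
    lab <- rgb_to_lab(fr)
    mask <- segment_coral(fr, labeller, clean_radius = clean_radius)
    if (!is.null(fr$valid)) mask <- mask & fr$valid
    if (!any(mask)) { out$status[i] <- "empty_mask"; next }
    mc <- mean_color(lab, mask)
    out$xi_a[i] <- mc["a"]; out$L[i] <- mc["L"]; out$b[i] <- mc["b"]
    out$mask_area_px[i] <- attr(mc, "n_px")
  }
  if (all(out$status != "ok")) rp_stop("every frame failed colour extraction")
  class(out) <- c("color_series", class(out))
  out
}

#' Convert a measurement table to an irregular series
#'
#' Extracts one value column of a `color_series` / `activity_series`
#' table as an [irregular_series()], dropping failed (NA) rows, i.e.
#' keeping gaps implicit.
#'
#' @param x a `color_series` or `activity_series` data.frame.
#' @param column value column (default: the series' own value, `xi_a` or
#'   `gamma`).
#' @return an [irregular_series()].
#' @export
as_series <- function(x, column = NULL) {
  if (is.null(column))
    column <- if (inherits(x, "activity_series")) "gamma" else "xi_a"
  ok <- !is.na(x[[column]])
  irregular_series(x$time_h[ok], x[[column]][ok], name = column)
}

#' Write a colour series as CSV
#' @param x a `color_series`.
#' @param path output file.
#' @export
write_color_series <- function(x, path) {
  out <- x
  out$timestamp <- format(hours_to_posix(out$time_h), "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out[, c("timestamp", "xi_a", "L", "b", "mask_area_px",
                           "status")],
                   path, row.names = FALSE)
  invisible(path)
}
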