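# The image container: a time-stamped RGB raster in [0, 1].

#' Construct an image frame
#'
#' @param data numeric array `height x width x 3`, values in \[0, 1\].
#' @param timestamp frame time (numeric hours or POSIXct); may be `NA`.
#' @param valid optional logical `height x width` matrix flagging pixels
#'   usable for analysis (e.g. borders invalidated by alignment).
#' @return object of class `reef_frame`.
#' @export
reef_frame <- function(data, timestamp = NA, valid = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L || dim(data)[3] != 3L)
    rp_stop("frame data must be a height x width x 3 array")
  if (dim(data)[1] < 1L || dim(data)[2] < 1L) rp_stop("empty frame")
  if (min(data) < -1e-9 || max(data) > 1 + 1e-9)
    rp_stop("frame values must lie in [0, 1]")
  ts <- if (length(timestamp) == 1L && is.na(timestamp)) NA_real_
        else time_to_hours(timestamp)
  if (!is.null(valid) && !identical(dim(valid), dim(data)[1:2]))
    rp_stop("valid mask dimensions must match the frame")
  structure(list(data = data, timestamp = ts, valid = valid),
            class = "reef_frame")
}

#' @export
print.reef_frame <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<reef_frame> %dx%d px, t=%s\n", d[2], d[1],
              if (is.na(x$timestamp)) "NA"
              else format(hours_to_posix(x$timestamp), "%Y-%m-%dT%H:%M:%SZ")))
  invisible(x)
}

#' Frame luminance (grayscale) channel
#' @param frame a `reef_frame` or an RGB array.
#' @return numeric matrix (Rec. 601 luma).
#' @export
frame_gray <- function(frame) {
  d <- if (inherits(frame, "reef_frame")) frame$data else frame
  0.299 * d[, , 1] + 0.587 * d[, , 2] + 0.114 * d[, , 3]
}

#' Write / read a frame as PNG
#'
#' Frames are written 8-bit, named `<ISO8601 timestamp>.png` when written
#' via [write_frames()].
#'
#' @param frame a `reef_frame`.
#' @param path output file.
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(frame$data, path)
  invisible(path)
}

#' @rdname write_frame_png
#' @param timestamp timestamp to attach on read (default parsed from the
#'   file name when it looks like an ISO8601 stamp).
#' @export
read_frame_png <- function(path, timestamp = NULL) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (is.null(timestamp)) {
    stem <- sub("\\.png$", "", basename(path), ignore.case = TRUE)
    ts <- suppressWarnings(as.POSIXct(stem, tz = "UTC",
                                      tryFormats = c("%Y-%m-%dT%H%M%SZ",
                                                     "%Y-%m-%dT%H:%M:%SZ",
                                                     "%Y-%m-%d %H:%M:%S")))
    timestamp <- if (is.na(ts)) NA else ts
  }
  reef_frame(a, timestamp = timestamp)
}

#' Write a frame sequence to a directory
#'
#' @param frames list of `reef_frame`s with timestamps.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(frames, function(f) {
    if (is.na(f$timestamp)) rp_stop("frame without timestamp")
    file.path(dir, paste0(format(hours_to_posix(f$timestamp),
                                 "%Y-%m-%dT%H%M%SZ"), ".png"))
  }, character(1))
  for (i in seq_along(frames)) write_frame_png(frames[[i]], paths[i])
  invisible(paths)
}

#' Read all frames from a directory, time-ordered
#' @param dir directory of `.png` frames named by ISO8601 timestamp.
#' @return list of `reef_frame`s sorted by timestamp.
#' @export
read_frames <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) rp_stop("no PNG frames in %s", dir)
  frames <- lapply(files, read_frame_png)
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  frames[order(ts)]
}
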