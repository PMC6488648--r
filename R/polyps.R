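# Polyp annotations, masks and patch datasets.
#
# Human experts mark polyp positions as points labelled active (extended,
# feeding) or inactive (retracted).  The union of small discs around all
# annotated points forms the polyp mask M; 46x46 patches centred on the
# annotations train the patch classifier, with random background patches
# sampled outside the mask.

#' Read / write annotation tables
#'
#' Point-annotation CSV with columns `image,x,y,class,annotator` (the
#' layout exported by point-labelling tools).
#'
#' @param path CSV file.
#' @return data.frame of class `annotation_set`.
#' @export
read_annotations <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image", "x", "y", "class", "annotator")
  if (!all(need %in% names(a)))
    rp_stop("annotation table must have columns %s", paste(need, collapse = ","))
  class(a) <- c("annotation_set", class(a))
  a
}

#' @rdname read_annotations
#' @param annotations an `annotation_set`.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(
    annotations[, c("image", "x", "y", "class", "annotator")],
    path, row.names = FALSE)
  invisible(path)
}

#' Build the polyp mask from point annotations
#'
#' Union of discs of `disc_radius` around every annotated point (both
#' classes, all annotators), clipped to the region of interest.  The
#' default radius of 23 px is half the 46 px classification patch, tying
#' the mask extent to the patch footprint.
#'
#' @param annotations an `annotation_set` (or data.frame with `x`, `y`).
#' @param roi either `c(height, width)` of the raster or a logical ROI
#'   matrix the mask is clipped to.
#' @param disc_radius disc radius in pixels (Euclidean distance <= radius).
#' @return logical `height x width` polyp mask.
#' @export
build_polyp_mask <- function(annotations, roi, disc_radius = 23) {
  if (nrow(annotations) == 0L) rp_stop("empty annotation set")
  if (is.matrix(roi)) { h <- nrow(roi); w <- ncol(roi) }
  else { h <- roi[1]; w <- roi[2] }
  mask <- matrix(FALSE, h, w)
  r <- disc_radius
  off <- expand.grid(dy = -ceiling(r):ceiling(r), dx = -ceiling(r):ceiling(r))
  off <- off[off$dx^2 + off$dy^2 <= r^2, ]
  for (i in seq_len(nrow(annotations))) {
    cx <- round(annotations$x[i]); cy <- round(annotations$y[i])
    ys <- cy + off$dy; xs <- cx + off$dx
    ok <- ys >= 1 & ys <= h & xs >= 1 & xs <= w
    mask[cbind(ys[ok], xs[ok])] <- TRUE
  }
  if (is.matrix(roi)) mask <- mask & roi
  mask
}

#' Construct an (empty) patch set
#'
#' A patch set stores `n` square RGB tiles as rows of a numeric matrix
#' (vectorized `size x size x 3` arrays) plus per-patch metadata: `label`,
#' `split`, `source_id` (the originating annotation; augmentation
#' descendants share it), `image`, `cx`, `cy`, `aug_op`.
#'
#' @param patches numeric matrix `n x (size*size*3)`.
#' @param meta data.frame with the columns above.
#' @param size patch edge length in pixels.
#' @return object of class `patch_set`.
#' @export
patch_set <- function(patches, meta, size = 46L) {
  if (nrow(patches) != nrow(meta)) rp_stop("patches/meta row mismatch")
  if (ncol(patches) != size * size * 3L)
    rp_stop("patch width %d does not match size %d", ncol(patches), size)
  structure(list(patches = patches, meta = meta, size = as.integer(size)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches %dx%d, labels: %s\n",
              nrow(x$patches), x$size, x$size,
              paste(sprintf("%s=%d", names(table(x$meta$label)),
                            table(x$meta$label)), collapse = " ")))
  invisible(x)
}

#' Number of patches
#' @param x a `patch_set`.
#' @export
n_patches <- function(x) nrow(x$patches)

#' Concatenate patch sets
#' @param ... `patch_set`s of equal patch size.
#' @return combined `patch_set`.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, n_patches, integer(1)) > 0L]
  if (!length(sets)) rp_stop("no patches to bind")
  sz <- unique(vapply(sets, function(s) s$size, integer(1)))
  if (length(sz) != 1L) rp_stop("patch sizes differ")
  patch_set(do.call(rbind, lapply(sets, function(s) s$patches)),
            do.call(rbind, lapply(sets, function(s) s$meta)), sz)
}

# One patch as a size x size x 3 array.
patch_array <- function(ps, i) array(ps$patches[i, ], c(ps$size, ps$size, 3L))

#' Extract square patches centred on annotated points
#'
#' A patch of `size x size` pixels is cut around each centre; centres too
#' close to the border for a full patch are skipped and reported via the
#' `skipped` attribute.
#'
#' @param frame a [reef_frame()].
#' @param centres data.frame with `x`, `y` and optionally `class` (stored
#'   as the patch label), `image`, `annotator`.
#' @param size patch edge length (46 px by default, the classification
#'   patch size).
#' @param source_offset integer added to the source ids (to keep ids
#'   unique across frames).
#' @return a [patch_set()]; attribute `skipped` holds the row indices of
#'   skipped centres.
#' @export
extract_patches <- function(frame, centres, size = 46L, source_offset = 0L) {
  stopifnot(inherits(frame, "reef_frame"))
  d <- dim(frame$data); h <- d[1]; w <- d[2]
  lo <- (size - 1L) %/% 2L; hi <- size - 1L - lo
  cx <- round(centres$x); cy <- round(centres$y)
  ok <- cx - lo >= 1L & cx + hi <= w & cy - lo >= 1L & cy + hi <= h
  idx <- which(ok)
  P <- matrix(0, length(idx), size * size * 3L)
  for (j in seq_along(idx)) {
    i <- idx[j]
    P[j, ] <- frame$data[(cy[i] - lo):(cy[i] + hi),
                         (cx[i] - lo):(cx[i] + hi), ]
  }
  lab <- if (!is.null(centres$class)) as.character(centres$class)[idx]
         else rep(NA_character_, length(idx))
  img <- if (!is.null(centres$image)) centres$image[idx]
         else rep(NA_integer_, length(idx))
  meta <- data.frame(label = lab, split = NA_character_,
                     source_id = source_offset + idx,
                     image = img, cx = cx[idx], cy = cy[idx],
                     aug_op = "orig", stringsAsFactors = FALSE)
  out <- patch_set(P, meta, size)
  attr(out, "skipped") <- which(!ok)
  out
}

#' Sample background patches outside the polyp mask
#'
#' Random patch centres in the ROI where the polyp mask is 0 (and a full
#' patch fits), labelled `"background"`.
#'
#' @param frame a [reef_frame()].
#' @param mask logical polyp mask (same size as the frame).
#' @param n number of background patches (100 by default, matching common annotation practice for a single ROI).
#' @param size patch edge length.
#' @param seed RNG seed.
#' @param source_offset as in [extract_patches()].
#' @return a [patch_set()].
#' @export
sample_background <- function(frame, mask, n = 100L, size = 46L, seed = 1,
                              source_offset = 0L) {
  d <- dim(frame$data); h <- d[1]; w <- d[2]
  lo <- (size - 1L) %/% 2L; hi <- size - 1L - lo
  feasible <- !mask
  feasible[c(seq_len(lo), (h - hi + 1L):h), ] <- FALSE
  feasible[, c(seq_len(lo), (w - hi + 1L):w)] <- FALSE
  cand <- which(feasible, arr.ind = TRUE)
  if (nrow(cand) < n)
    rp_stop("only %d feasible background centres for n=%d", nrow(cand), n)
  set.seed(seed)
  pick <- cand[sample(nrow(cand), n), , drop = FALSE]
  centres <- data.frame(x = pick[, 2], y = pick[, 1], class = "background")
  extract_patches(frame, centres, size, source_offset = source_offset)
}
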