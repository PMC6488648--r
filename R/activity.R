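# The polyp activity series: classify every polyp-mask pixel with the
# patch network and report the active fraction per frame.

#' Classify polyp-mask pixels of a frame
#'
#' Applies the patch classifier to the 46x46 patch centred at each pixel
#' inside the polyp mask.  With `stride > 1` only a subgrid is evaluated
#' and the remaining masked pixels take the value of their nearest
#' evaluated neighbour (a documented compute/accuracy trade-off; stride 1
#' is the exact, brute-force evaluation).
#'
#' @param frame a [reef_frame()] (registered to the reference on which the
#'   mask was defined).
#' @param mask logical polyp mask, same size as the frame.
#' @param clf a [train_classifier()] result.
#' @param stride evaluation stride in pixels (>= 1).
#' @param threshold likelihood threshold for the binary activity map.
#' @param batch classifier batch size.
#' @return list with `likelihood` (numeric matrix, `NA` outside the mask
#'   and at masked pixels whose patch does not fit in the frame),
#'   `active` (logical matrix: likelihood >= threshold), and `n_skipped`
#'   (masked pixels without a feasible patch).
#' @export
classify_pixels <- function(frame, mask, clf, stride = 2L, threshold = 0.5,
                            batch = 96L) {
  stopifnot(inherits(frame, "reef_frame"))
  d <- dim(frame$data); h <- d[1]; w <- d[2]
  if (!identical(dim(mask), c(h, w))) rp_stop("mask/frame size mismatch")
  if (!any(mask)) rp_stop("empty polyp mask")
  if (stride < 1L) rp_stop("stride must be >= 1")
  size <- clf$size
  lo <- (size - 1L) %/% 2L; hi <- size - 1L - lo

  feas <- mask
  feas[c(seq_len(min(lo, h)), max(h - hi + 1L, 1L):h), ] <- FALSE
  feas[, c(seq_len(min(lo, w)), max(w - hi + 1L, 1L):w)] <- FALSE
  n_skipped <- sum(mask) - sum(feas)

  px <- which(feas, arr.ind = TRUE)
  sub <- px[(px[, 1] - 1L) %% stride == 0L & (px[, 2] - 1L) %% stride == 0L,
            , drop = FALSE]
  if (nrow(sub) == 0L) sub <- px[1L, , drop = FALSE]
  centres <- data.frame(x = sub[, 2], y = sub[, 1])
  ps <- extract_patches(frame, centres, size = size)
  lik_sub <- predict_classifier(clf, ps, type = "likelihood", batch = batch)

  likelihood <- matrix(NA_real_, h, w)
  likelihood[sub] <- lik_sub
  if (stride > 1L && nrow(px) > nrow(sub)) {
    # nearest-fill: snap each feasible pixel to the closest evaluated
    # subgrid coordinate (clamped to the evaluated range)
    snap <- function(v, grid_max) pmin(round((v - 1L) / stride) * stride + 1L,
                                       grid_max)
    ys <- snap(px[, 1], max(sub[, 1])); xs <- snap(px[, 2], max(sub[, 2]))
    filled <- likelihood[cbind(ys, xs)]
    # pixels that snapped to an unevaluated spot fall back to their own
    # value (NA) — resolve by nearest evaluated pixel among the subgrid
    miss <- is.na(filled)
    if (any(miss)) {
      for (i in which(miss)) {
        dd <- (sub[, 1] - px[i, 1])^2 + (sub[, 2] - px[i, 2])^2
        filled[i] <- lik_sub[which.min(dd)]
      }
    }
    likelihood[px] <- filled
  }
  active <- likelihood >= threshold
  list(likelihood = likelihood, active = active, n_skipped = n_skipped)
}

#' Polyp activity of one frame
#'
#' The fraction of polyp-mask pixels classified active: the count of
#' masked pixels whose binary activity is TRUE over the count of masked
#' pixels with a defined classification.
#'
#' @param active logical activity raster (e.g. `classify_pixels()$active`);
#'   `NA` marks masked pixels without a classification.
#' @param mask logical polyp mask, congruent with `active`.
#' @return activity fraction in \[0, 1\]; attributes `n_active`,
#'   `n_masked` (evaluated masked pixels) and `n_unscored`.
#' @export
polyp_activity <- function(active, mask) {
  if (!identical(dim(active), dim(mask))) rp_stop("raster/mask mismatch")
  if (!any(mask)) rp_stop("empty polyp mask")
  vals <- active[mask]
  n_eval <- sum(!is.na(vals))
  if (n_eval == 0L) rp_stop("no masked pixel has a classification")
  g <- sum(vals, na.rm = TRUE) / n_eval
  structure(g, n_active = sum(vals, na.rm = TRUE), n_masked = n_eval,
            n_unscored = sum(is.na(vals)))
}

#' Compute the polyp activity series over a frame sequence
#'
#' Per frame: register to the reference that defines the mask, classify
#' the masked pixels, and record the active fraction.  Frames failing
#' registration or classification become gaps.
#'
#' @param frames time-ordered list of [reef_frame()]s.
#' @param mask logical polyp mask defined on the reference frame.
#' @param clf a [train_classifier()] result.
#' @param reference reference frame (default: first frame).
#' @param register align frames before classification.
#' @param stride,threshold see [classify_pixels()].
#' @param min_quality,max_shift registration failure thresholds.
#' @return an `activity_series` data.frame: `time_h`, `gamma`,
#'   `n_masked_px`, `status`; failed frames keep `NA` gamma (gaps).
#' @export
activity_series <- function(frames, mask, clf, reference = NULL,
                            register = TRUE, stride = 2L, threshold = 0.5,
                            min_quality = 0.05, max_shift = 64) {
  if (!length(frames)) rp_stop("no frames")
  ts <- vapply(frames, function(f) f$timestamp, numeric(1))
  if (anyNA(ts)) rp_stop("all frames need timestamps")
  if (is.unsorted(ts, strictly = TRUE)) rp_stop("frames must be time-ordered")
  if (is.null(reference)) reference <- frames[[1L]]
  out <- data.frame(time_h = ts, gamma = NA_real_, n_masked_px = NA_integer_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (register) {
      reg <- register_frame(fr, reference, min_quality = min_quality,
                            max_shift = max_shift)
      if (!reg$success) { out$status[i] <- "alignment_failure"; next }
      fr <- reg$frame
    }
    res <- tryCatch(classify_pixels(fr, mask, clf, stride = stride,
                                    threshold = threshold),
                    error = function(e) NULL)
    if (is.null(res)) { out$status[i] <- "classification_failure"; next }
    g <- polyp_activity(res$active, mask)
    out$gamma[i] <- as.numeric(g)
    out$n_masked_px[i] <- attr(g, "n_masked")
  }
  if (all(out$status != "ok")) rp_stop("every frame failed activity extraction")
  class(out) <- c("activity_series", class(out))
  out
}

#' Write an activity series as CSV
#' @param x an `activity_series`.
#' @param path output file.
#' @export
write_activity_series <- function(x, path) {
  out <- x
  out$timestamp <- format(hours_to_posix(out$time_h), "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out[, c("timestamp", "gamma", "n_masked_px", "status")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Agreement between two point-annotation sets
#'
#' Greedy nearest-neighbour matching within `match_radius` (per image):
#' the closest remaining pair is matched until none is within range.
#' Agreement = (matched pairs with equal class) / (matched pairs +
#' unmatched points of either set), so missed or extra detections count
#' as disagreement.
#'
#' @param a,b `annotation_set`s over the same images.
#' @param match_radius maximum matching distance in pixels.
#' @return agreement in \[0, 1\]; attributes `n_matched`, `n_agree`,
#'   `n_unmatched`.
#' @export
observer_agreement <- function(a, b, match_radius = 23) {
  if (nrow(a) == 0L && nrow(b) == 0L) rp_stop("both annotation sets empty")
  imgs <- union(unique(a$image), unique(b$image))
  n_match <- 0L; n_agree <- 0L; n_un <- 0L
  for (im in imgs) {
    ai <- a[a$image == im, , drop = FALSE]
    bi <- b[b$image == im, , drop = FALSE]
    if (nrow(ai) == 0L || nrow(bi) == 0L) {
      n_un <- n_un + nrow(ai) + nrow(bi)
      next
    }
    D <- outer(ai$x, bi$x, `-`)^2 + outer(ai$y, bi$y, `-`)^2
    D <- sqrt(D)
    free_a <- rep(TRUE, nrow(ai)); free_b <- rep(TRUE, nrow(bi))
    repeat {
      D2 <- D
      D2[!free_a, ] <- Inf; D2[, !free_b] <- Inf
      m <- which.min(D2)
      if (!length(m) || D2[m] > match_radius) break
      ia <- (m - 1L) %% nrow(ai) + 1L
      ib <- (m - 1L) %/% nrow(ai) + 1L
      free_a[ia] <- FALSE; free_b[ib] <- FALSE
      n_match <- n_match + 1L
      if (ai$class[ia] == bi$class[ib]) n_agree <- n_agree + 1L
      if (!any(free_a) || !any(free_b)) break
    }
    n_un <- n_un + sum(free_a) + sum(free_b)
  }
  denom <- n_match + n_un
  structure(if (denom == 0L) 0 else n_agree / denom,
            n_matched = n_match, n_agree = n_agree, n_unmatched = n_un)
}

#' Manual polyp activity from annotations
#'
#' The count-based activity a human annotation set implies: the fraction
#' of annotated polyps labelled active (optionally restricted to points
#' inside a mask).
#'
#' @param annotations an `annotation_set`.
#' @param mask optional logical mask; annotations outside it are ignored.
#' @return fraction of active annotations in \[0, 1\].
#' @export
manual_gamma <- function(annotations, mask = NULL) {
  a <- annotations
  if (!is.null(mask)) {
    xi <- pmin(pmax(round(a$x), 1L), ncol(mask))
    yi <- pmin(pmax(round(a$y), 1L), nrow(mask))
    a <- a[mask[cbind(yi, xi)], , drop = FALSE]
  }
  if (nrow(a) == 0L) rp_stop("no annotations to score")
  mean(a$class == "active")
}
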