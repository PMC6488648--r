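# Patch augmentation (flip x2, rotate x12, noise x2 = factor 48) and
# source-level train/validation/test splitting.

# Sparse bilinear-resampling operator for rotating a size x size grid by
# `angle` (radians) about its centre, with border reflection.  Returns a
# (size^2 x size^2) sparse matrix applied per colour channel.
rotation_operator <- function(size, angle) {
  c0 <- (size + 1) / 2
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  ca <- cos(angle); sa <- sin(angle)
  xs <- c0 + (g$x - c0) * ca - (g$y - c0) * sa
  ys <- c0 + (g$x - c0) * sa + (g$y - c0) * ca
  reflect <- function(v) {
    # reflect into [1, size] (period 2*(size-1))
    v <- abs(v - 1) %% (2 * (size - 1))
    1 + ifelse(v > size - 1, 2 * (size - 1) - v, v)
  }
  xs <- reflect(xs); ys <- reflect(ys)
  x0 <- pmin(floor(xs), size - 1); y0 <- pmin(floor(ys), size - 1)
  fx <- xs - x0; fy <- ys - y0
  n <- size * size
  row <- rep(seq_len(n), 4L)
  col <- c(y0 + size * (x0 - 1), y0 + 1 + size * (x0 - 1),
           y0 + size * x0, y0 + 1 + size * x0)
  wgt <- c((1 - fy) * (1 - fx), fy * (1 - fx), (1 - fy) * fx, fy * fx)
  Matrix::sparseMatrix(i = row, j = col, x = wgt, dims = c(n, n))
}

# Apply a size^2 x size^2 spatial operator to every channel of a patch
# matrix (n x size^2*3).
apply_spatial_op <- function(P, op, size) {
  n2 <- size * size
  out <- P
  for (c in 0:2) {
    cols <- c * n2 + seq_len(n2)
    out[, cols] <- as.matrix(P[, cols, drop = FALSE] %*% Matrix::t(op))
  }
  out
}

# Horizontal flip as a column permutation of the patch matrix.
flip_permutation <- function(size) {
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  perm2 <- g$y + size * (size - g$x)     # mirrored x
  as.vector(outer(perm2, (0:2) * size * size, `+`))
}

#' Augment a patch set by flips, rotations and noise
#'
#' Every input patch is expanded into
#' `{identity, horizontal flip} x {12 rotations in 30 degree steps} x
#' {clean, + Gaussian noise}` = 48 output patches.  Rotation resamples
#' bilinearly with border reflection; the 0-degree rotation is an exact
#' identity, so the original patch is among the outputs.  Provenance
#' (`aug_op`, inherited `source_id`) is recorded per output patch.
#'
#' @param ps a [patch_set()].
#' @param noise_sd sd of the additive Gaussian noise, in units of the
#'   \[0, 1\] dynamic range (default 2%).
#' @param n_rotations number of rotation steps (12 by default: 30-degree steps).
#' @param seed RNG seed for the noise draws.
#' @return a [patch_set()] with `48 * n_patches(ps)` rows.
#' @export
augment_patches <- function(ps, noise_sd = 0.02, n_rotations = 12L, seed = 1) {
  stopifnot(inherits(ps, "patch_set"))
  n <- n_patches(ps)
  if (n == 0L) return(ps)
  size <- ps$size
  angles <- 2 * pi * (seq_len(n_rotations) - 1L) / n_rotations
  fperm <- flip_permutation(size)
  set.seed(seed)
  blocks <- list(); metas <- list()
  for (flip in c(FALSE, TRUE)) {
    base <- if (flip) ps$patches[, fperm, drop = FALSE] else ps$patches
    for (a in seq_along(angles)) {
      rot <- if (angles[a] == 0) base else
        pmin(pmax(apply_spatial_op(base, rotation_operator(size, angles[a]),
                                   size), 0), 1)
      for (noisy in c(FALSE, TRUE)) {
        out <- if (noisy)
          pmin(pmax(rot + matrix(rnorm(length(rot), sd = noise_sd),
                                 nrow(rot)), 0), 1) else rot
        m <- ps$meta
        m$aug_op <- sprintf("%s_rot%03d%s", if (flip) "flip" else "id",
                            round(angles[a] * 180 / pi),
                            if (noisy) "_noise" else "")
        blocks[[length(blocks) + 1L]] <- out
        metas[[length(metas) + 1L]] <- m
      }
    }
  }
  patch_set(do.call(rbind, blocks), do.call(rbind, metas), size)
}

#' Assign train/validation/test splits at the source-annotation level
#'
#' Splits are drawn over unique `source_id`s, so every augmented
#' descendant of an annotation lands in the same split and no augmented
#' copy of a validation/test patch can leak into training.  Sources are
#' shuffled within label groups and interleaved before cutting, keeping
#' the global 70/20/10 counts exact while balancing classes across splits.
#'
#' @param ps a [patch_set()].
#' @param fractions `c(train, validation, test)` fractions summing to 1.
#' @param seed RNG seed.
#' @return the `patch_set` with `meta$split` filled in.
#' @export
split_dataset <- function(ps, fractions = c(0.7, 0.2, 0.1), seed = 1) {
  stopifnot(inherits(ps, "patch_set"))
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions < 0) ||
      any(fractions > 1))
    rp_stop("fractions must be in [0,1] and sum to 1")
  src <- unique(ps$meta[, c("source_id", "label")])
  set.seed(seed)
  by_lab <- split(src$source_id, src$label)
  by_lab <- lapply(by_lab, sample)
  # interleave label groups so each split sees every class
  ord <- unlist(lapply(seq_len(max(lengths(by_lab))), function(i)
    unlist(lapply(by_lab, function(v) if (i <= length(v)) v[i] else NULL))))
  n <- length(ord)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  n_te <- n - n_tr - n_va
  lab <- rep(c("train", "val", "test"), times = c(n_tr, n_va, n_te))
  assign <- setNames(lab, ord)
  ps$meta$split <- unname(assign[as.character(ps$meta$source_id)])
  ps
}
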