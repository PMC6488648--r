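# Synthetic reef scenes with known ground truth.
#
# A scene is rendered in CIELab: the live-coral region carries an oriented
# band-pass texture and a controllable tissue redness (a* level); the
# background carries a second texture at a different wavelength and
# orientation.  Extended (active) polyps are drawn as radially-armed star
# blobs about one patch (~46 px) across; retracted (inactive) polyps as
# smooth darker discs.  The Lab canvas is converted to sRGB, quantized to
# 8 bits, perturbed by small sensor noise, and cropped at the frame's
# translation offset to emulate camera jitter.

#' Ground truth of one synthetic frame
#'
#' @param coral_region logical `height x width` matrix: TRUE = live coral.
#' @param polyp_centres data.frame with `x`, `y` (pixels, x = column,
#'   y = row) and `state` (`"active"`/`"inactive"`); all centres must lie
#'   inside `coral_region`.
#' @param redness_a target tissue a* value (CIELab a units).
#' @param frame_shift integer `c(dx, dy)` translation of the frame content
#'   in pixels.
#' @param id optional frame identifier (used by annotation tables).
#' @return object of class `scene_truth`.
#' @export
scene_truth <- function(coral_region, polyp_centres =
                          data.frame(x = numeric(), y = numeric(),
                                     state = character()),
                        redness_a = 0, frame_shift = c(0L, 0L), id = NULL) {
  if (!is.matrix(coral_region) || !is.logical(coral_region))
    rp_stop("coral_region must be a logical matrix")
  polyp_centres <- as.data.frame(polyp_centres)
  rp_num1(redness_a, "redness_a")
  if (nrow(polyp_centres)) {
    if (!all(polyp_centres$state %in% c("active", "inactive")))
      rp_stop("polyp state must be 'active' or 'inactive'")
    xi <- round(polyp_centres$x); yi <- round(polyp_centres$y)
    h <- nrow(coral_region); w <- ncol(coral_region)
    if (any(xi < 1 | xi > w | yi < 1 | yi > h))
      rp_stop("polyp centre outside the raster")
    if (!all(coral_region[cbind(yi, xi)]))
      rp_stop("polyp centre outside the coral region")
  }
  structure(list(coral_region = coral_region,
                 polyp_centres = polyp_centres,
                 redness_a = redness_a,
                 frame_shift = as.integer(round(frame_shift)),
                 id = id),
            class = "scene_truth")
}

#' Rendering parameters of the synthetic scene
#'
#' The two textures are filtered-noise fields band-passed by a Gabor
#' kernel, so a Gabor bank separates them; defaults put the coral texture
#' at 8 px wavelength / 30 degrees and the background at 18 px / 120
#' degrees.
#'
#' @param coral_wavelength,coral_orientation coral texture carrier.
#' @param bg_wavelength,bg_orientation background texture carrier.
#' @param texture_amp texture luminance amplitude (L units, 1 sd).
#' @param coral_L,bg_L base luminance of the two regions.
#' @param coral_b,bg_b base b* (yellow-blue) of the two regions.
#' @param bg_a background a* (red-green) level.
#' @param polyp_radius polyp footprint radius in pixels (~half the 46 px
#'   classification patch).
#' @param noise_sd per-frame sensor noise sd in RGB units (of 1).
#' @param texture_seed seed of the static scene texture (shared by all
#'   frames of a sequence so that frames differ only by shift, polyp state
#'   and sensor noise).
#' @return list of class `texture_params`.
#' @export
texture_params <- function(coral_wavelength = 8, coral_orientation = pi / 6,
                           bg_wavelength = 18, bg_orientation = 2 * pi / 3,
                           texture_amp = 5, coral_L = 58, bg_L = 46,
                           coral_b = 10, bg_b = -4, bg_a = -6,
                           polyp_radius = 22, noise_sd = 0.004,
                           texture_seed = 99) {
  structure(as.list(environment()), class = "texture_params")
}

# Oriented band-pass noise field, unit sd.
oriented_texture <- function(h, w, wavelength, orientation, seed) {
  set.seed(seed)
  k <- gabor_kernel(wavelength, orientation)
  f <- EBImage::filter2(matrix(rnorm(h * w), h, w), k$even)
  f / sd(f)
}

# Star-shaped radial weight for an active polyp: arms as a cosine-lobed
# radius profile; returns weight in [0, 1] over the local window.
star_weight <- function(dx, dy, r_out, n_arms, rot) {
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  prof <- r_out * (0.35 + 0.65 * (0.5 + 0.5 * cos(n_arms * (th + rot)))^1.5)
  core <- pmax(0, 1 - r / (0.25 * r_out))
  arm <- as.numeric(r <= prof) * pmax(0, 1 - r / r_out)^0.35
  pmin(1, pmax(arm, core))
}

# Smooth disc weight for an inactive polyp.
disc_weight <- function(dx, dy, r) {
  d <- sqrt(dx^2 + dy^2)
  pmin(1, pmax(0, (r - d) / 2 + 0.5))
}

# Render the static Lab scene (no shift, no sensor noise) on a canvas with
# `margin` extra pixels on every side.  Textures come from
# params$texture_seed; polyp arm geometry from `polyp_seed` so a polyp
# keeps its arm count/rotation across frames.
render_scene_lab <- function(truth, params, margin, textures = NULL) {
  h <- nrow(truth$coral_region); w <- ncol(truth$coral_region)
  H <- h + 2L * margin; W <- w + 2L * margin
  if (is.null(textures)) {
    textures <- list(
      coral = oriented_texture(H, W, params$coral_wavelength,
                               params$coral_orientation, params$texture_seed),
      bg = oriented_texture(H, W, params$bg_wavelength,
                            params$bg_orientation, params$texture_seed + 1L))
  }
  # coral region extended onto the canvas by edge replication
  if (margin > 0L) {
    ridx <- c(rep(1L, margin), seq_len(h), rep(h, margin))
    cidx <- c(rep(1L, margin), seq_len(w), rep(w, margin))
    reg <- truth$coral_region[ridx, cidx]
  } else {
    reg <- truth$coral_region
  }
  L <- ifelse(reg, params$coral_L, params$bg_L) +
    params$texture_amp * ifelse(reg, textures$coral, textures$bg)
  A <- ifelse(reg, truth$redness_a, params$bg_a)
  B <- ifelse(reg, params$coral_b, params$bg_b)

  pc <- truth$polyp_centres
  if (nrow(pc)) {
    r_out <- params$polyp_radius
    for (i in seq_len(nrow(pc))) {
      cx <- round(pc$x[i]) + margin; cy <- round(pc$y[i]) + margin
      win <- -(r_out + 2):(r_out + 2)
      xs <- cx + win; ys <- cy + win
      ok_x <- xs >= 1 & xs <= W; ok_y <- ys >= 1 & ys <= H
      xs <- xs[ok_x]; ys <- ys[ok_y]
      g <- expand.grid(dy = ys - cy, dx = xs - cx)
      if (pc$state[i] == "active") {
        n_arms <- 6L + (i * 7L) %% 5L          # 6..10 arms, fixed per polyp
        rot <- (i * 2.399) %% (2 * pi)
        wgt <- star_weight(g$dx, g$dy, r_out, n_arms, rot)
        wm <- matrix(wgt, length(ys), length(xs))
        L[ys, xs] <- L[ys, xs] * (1 - wm) + wm * 82
        B[ys, xs] <- B[ys, xs] * (1 - wm) + wm * (params$coral_b + 4)
      } else {
        wgt <- disc_weight(g$dx, g$dy, r_out * 0.45)
        wm <- matrix(wgt, length(ys), length(xs))
        L[ys, xs] <- L[ys, xs] * (1 - wm) + wm * 38
        B[ys, xs] <- B[ys, xs] * (1 - wm) + wm * (params$coral_b - 2)
      }
      # a* left untouched: polyps modulate luminance/shape, not redness,
      # so the region-mean a* stays at the requested tissue level.
    }
  }
  list(L = L, A = A, B = B, textures = textures, margin = margin)
}

# Convert a rendered Lab scene to a cropped, quantized RGB frame.
scene_to_frame <- function(scene, truth, h, w, noise_sd, seed, timestamp = NA) {
  m <- scene$margin
  dx <- truth$frame_shift[1]; dy <- truth$frame_shift[2]
  if (abs(dx) > m || abs(dy) > m)
    rp_stop("frame_shift exceeds the render margin (%d px)", m)
  rows <- (m + seq_len(h)) - dy
  cols <- (m + seq_len(w)) - dx
  lab <- cbind(as.vector(scene$L[rows, cols]),
               as.vector(scene$A[rows, cols]),
               as.vector(scene$B[rows, cols]))
  rgb <- farver::convert_colour(lab, from = "lab", to = "rgb") / 255
  rgb <- pmin(pmax(rgb, 0), 1)
  set.seed(seed)
  if (noise_sd > 0) rgb <- rgb + rnorm(length(rgb), sd = noise_sd)
  rgb <- round(pmin(pmax(rgb, 0), 1) * 255) / 255
  reef_frame(array(rgb, c(h, w, 3)), timestamp = timestamp)
}

#' Render one synthetic reef frame
#'
#' @param truth a [scene_truth()].
#' @param params a [texture_params()].
#' @param seed per-frame RNG seed (sensor noise); the same truth, params
#'   and seed give a bit-identical frame.
#' @param margin render margin in pixels (must cover `abs(frame_shift)`).
#' @param timestamp optional frame time.
#' @return a [reef_frame()].
#' @export
generate_reef_frame <- function(truth, params = texture_params(), seed = 1,
                                margin = 16L, timestamp = NA) {
  stopifnot(inherits(truth, "scene_truth"))
  h <- nrow(truth$coral_region); w <- ncol(truth$coral_region)
  scene <- render_scene_lab(truth, params, margin)
  scene_to_frame(scene, truth, h, w, params$noise_sd, seed, timestamp)
}

#' Generate a smooth synthetic live-coral region
#'
#' Threshold of a low-pass random field biased towards the image centre,
#' giving one compact blob with an irregular boundary.
#'
#' @param width,height raster size in pixels.
#' @param coverage target fraction of coral pixels.
#' @param seed RNG seed.
#' @return logical `height x width` matrix.
#' @export
make_coral_region <- function(width = 512, height = 512, coverage = 0.45,
                              seed = 1) {
  set.seed(seed)
  f <- matrix(rnorm(height * width), height, width)
  f <- as.matrix(EBImage::gblur(EBImage::Image(f), sigma = min(width, height) / 10))
  f <- f / sd(f)
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  g <- expand.grid(y = seq_len(height), x = seq_len(width))
  rad <- sqrt(((g$x - cx) / width)^2 + ((g$y - cy) / height)^2)
  field <- f - matrix(3.5 * rad, height, width)
  field >= quantile(field, 1 - coverage)
}

#' Generate an hourly synthetic frame sequence with ground truth
#'
#' Renders `n_frames` hourly frames of a fixed scene.  Per frame, the
#' tissue redness follows `color_trajectory`, each polyp is active with
#' probability `activity_trajectory`, the content is shifted by integer
#' camera jitter, and a fraction of frames is dropped entirely (camera
#' malfunction), leaving gaps in the timestamp sequence.
#'
#' @param n_frames number of nominal hourly frames (>= 1).
#' @param color_trajectory per-frame target a* values (length `n_frames`,
#'   recycled if length 1).
#' @param activity_trajectory per-frame probability that a polyp is active
#'   (length `n_frames` or 1).
#' @param jitter_sd sd of the per-frame translation (pixels); shifts are
#'   rounded to whole pixels.
#' @param missing_fraction fraction of frames dropped at random in (0, 1\].
#' @param seed master RNG seed.
#' @param width,height frame size.
#' @param n_polyps polyps placed in the coral region.
#' @param params a [texture_params()].
#' @param start_time timestamp of frame 1 (hours or POSIXct).
#' @param coverage coral coverage passed to [make_coral_region()].
#' @return list with `frames` (list of [reef_frame()]), `truths` (list of
#'   [scene_truth()], same order), `dropped_times` (hours), and
#'   `region` (the shared coral region).
#' @export
generate_sequence <- function(n_frames, color_trajectory = 5,
                              activity_trajectory = 0.5, jitter_sd = 1,
                              missing_fraction = 0, seed = 1,
                              width = 512, height = 512, n_polyps = 12,
                              params = texture_params(),
                              start_time = 0, coverage = 0.45) {
  if (n_frames < 1L) rp_stop("n_frames must be >= 1")
  if (missing_fraction < 0 || missing_fraction >= 1)
    rp_stop("missing_fraction must be in [0, 1)")
  color_trajectory <- rep_len(color_trajectory, n_frames)
  activity_trajectory <- rep_len(activity_trajectory, n_frames)
  if (any(activity_trajectory < 0 | activity_trajectory > 1))
    rp_stop("activity_trajectory must be probabilities in [0, 1]")
  margin <- max(16L, ceiling(4 * jitter_sd))
  t0 <- time_to_hours(start_time)

  set.seed(seed)
  region <- make_coral_region(width, height, coverage, seed = seed + 1000L)
  centres <- place_polyps(region, n_polyps,
                          min_dist = 44, border = 26 + margin,
                          seed = seed + 2000L)

  # static textures rendered once on the padded canvas
  tex <- list(
    coral = oriented_texture(height + 2L * margin, width + 2L * margin,
                             params$coral_wavelength, params$coral_orientation,
                             params$texture_seed),
    bg = oriented_texture(height + 2L * margin, width + 2L * margin,
                          params$bg_wavelength, params$bg_orientation,
                          params$texture_seed + 1L))

  set.seed(seed)
  shifts <- matrix(as.integer(round(rnorm(2L * n_frames, sd = jitter_sd))),
                   ncol = 2L)
  shifts[abs(shifts) > margin] <- margin
  states <- matrix(runif(n_frames * nrow(centres)) <
                     rep(activity_trajectory, nrow(centres)),
                   nrow = n_frames)
  keep <- rep(TRUE, n_frames)
  if (missing_fraction > 0) {
    n_drop <- round(missing_fraction * n_frames)
    if (n_drop >= 1L) keep[sample(n_frames, n_drop)] <- FALSE
  }

  frames <- list(); truths <- list()
  for (i in seq_len(n_frames)) {
    if (!keep[i]) next
    st <- ifelse(states[i, ], "active", "inactive")
    truth <- scene_truth(region,
                         data.frame(x = centres$x, y = centres$y, state = st),
                         redness_a = color_trajectory[i],
                         frame_shift = shifts[i, ], id = i)
    scene <- render_scene_lab(truth, params, margin, textures = tex)
    fr <- scene_to_frame(scene, truth, height, width, params$noise_sd,
                         seed = seed + 3000L + i, timestamp = t0 + (i - 1))
    frames[[length(frames) + 1L]] <- fr
    truths[[length(truths) + 1L]] <- truth
  }
  list(frames = frames, truths = truths,
       dropped_times = t0 + which(!keep) - 1, region = region,
       polyp_centres = centres)
}

# Sample polyp centres inside the region, away from borders and from each
# other (greedy rejection; the spacing target relaxes down to one polyp
# radius when the region is too small for the requested count).
place_polyps <- function(region, n, min_dist = 44, border = 40, seed = 1) {
  set.seed(seed)
  h <- nrow(region); w <- ncol(region)
  ok <- which(region, arr.ind = TRUE)
  ok <- ok[ok[, 1] > border & ok[, 1] <= h - border &
           ok[, 2] > border & ok[, 2] <= w - border, , drop = FALSE]
  if (!nrow(ok)) rp_stop("coral region too small to place polyps")
  for (md in unique(pmax(c(min_dist, 36, 28, 22), 22))) {
    picked <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(picked) < n && tries < 20000L) {
      tries <- tries + 1L
      cand <- ok[sample(nrow(ok), 1L), ]
      if (nrow(picked) == 0L ||
          min(sqrt((picked[, 1] - cand[1])^2 +
                     (picked[, 2] - cand[2])^2)) >= md) {
        picked <- rbind(picked, cand)
      }
    }
    if (nrow(picked) == n)
      return(data.frame(x = picked[, 2], y = picked[, 1]))
  }
  rp_stop("could only place %d of %d polyps; lower n_polyps or enlarge the scene",
          nrow(picked), n)
}
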