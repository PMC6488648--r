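# Texture-driven pixel labelling: SOM vector quantization with per-node
# majority class, used to segment the live-coral region.
#
# The labeller is a flat rectangular self-organizing map trained on Gabor
# feature vectors of labelled seed pixels; each codebook node takes the
# majority class of the seed pixels it wins, and new pixels get the class
# of their nearest node.  (The class decision, not the lattice geometry,
# drives the mask.)

#' Train a SOM-based pixel labeller
#'
#' @param features numeric matrix `n x d` of per-pixel feature vectors
#'   (e.g. rows of [extract_gabor_features()] output via its internal
#'   flattening), or a `h x w x d` feature array with `labels` as a matrix.
#' @param labels character/factor vector of length `n` with classes
#'   `"coral"` / `"background"` (any two or more class names work); `NA`
#'   entries are ignored.
#' @param grid_dim SOM grid as `c(nx, ny)`.
#' @param n_train maximum number of seed pixels sampled per class for
#'   training (keeps the batch SOM fast on full-frame seeds).
#' @param seed RNG seed (sampling and SOM initialization).
#' @param bank the [gabor_bank()] the features came from; stored so
#'   [segment_coral()] can recompute matching features from raw frames.
#' @return object of class `pixel_labeller` with the codebook, per-node
#'   classes and feature scaling.
#' @export
train_pixel_labeller <- function(features, labels, grid_dim = c(6, 6),
                                 n_train = 4000, seed = 1,
                                 bank = gabor_bank()) {
  if (is.array(features) && length(dim(features)) == 3L)
    features <- feature_matrix(features)
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    rp_stop("labels length must match feature rows")
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]; labels <- labels[keep]
  classes <- sort(unique(labels))
  if (length(classes) < 2L) rp_stop("need seed pixels for at least 2 classes")
  cnt <- table(labels)
  if (any(cnt == 0L)) rp_stop("a class has zero seed pixels")

  set.seed(seed)
  idx <- unlist(lapply(classes, function(cl) {
    i <- which(labels == cl)
    if (length(i) > n_train) sample(i, n_train) else i
  }))
  X <- features[idx, , drop = FALSE]
  y <- labels[idx]
  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  grid <- class::somgrid(grid_dim[1], grid_dim[2], "rectangular")
  som <- class::batchSOM(Xs, grid, radii = c(4, 2, 1, 0.5))
  codes <- som$codes

  # assign nodes by majority vote of their winning seed pixels
  win <- nearest_node(Xs, codes)
  node_class <- rep(NA_character_, nrow(codes))
  for (k in seq_len(nrow(codes))) {
    yk <- y[win == k]
    if (length(yk)) node_class[k] <- names(which.max(table(yk)))
  }
  # nodes that won nothing inherit the class of the nearest labelled node
  if (anyNA(node_class)) {
    lab_idx <- which(!is.na(node_class))
    for (k in which(is.na(node_class))) {
      dk <- rowSums((codes[lab_idx, , drop = FALSE] -
                       matrix(codes[k, ], length(lab_idx), ncol(codes),
                              byrow = TRUE))^2)
      node_class[k] <- node_class[lab_idx[which.min(dk)]]
    }
  }
  structure(list(codes = codes, node_class = node_class, classes = classes,
                 center = ctr, scale = scl, grid_dim = grid_dim,
                 bank = bank, seed = seed),
            class = "pixel_labeller")
}

#' @export
print.pixel_labeller <- function(x, ...) {
  cat(sprintf("<pixel_labeller> %dx%d SOM, %d features, classes: %s\n",
              x$grid_dim[1], x$grid_dim[2], ncol(x$codes),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Winning codebook node per row of X (argmin distance == argmax of the
# inner product minus half the squared code norm; avoids the full n x k
# distance matrix).
nearest_node <- function(X, codes) {
  s <- X %*% t(codes)
  s <- sweep(s, 2, 0.5 * rowSums(codes^2))
  max.col(s, ties.method = "first")
}

#' Classify feature vectors with a trained pixel labeller
#'
#' @param labeller a `pixel_labeller`.
#' @param features `n x d` matrix or `h x w x d` array.
#' @return character vector (or matrix, for array input) of class labels.
#' @export
predict_pixels <- function(labeller, features) {
  is_arr <- is.array(features) && length(dim(features)) == 3L
  dm <- if (is_arr) dim(features) else NULL
  X <- if (is_arr) feature_matrix(features) else features
  Xs <- sweep(sweep(X, 2, labeller$center), 2, labeller$scale, "/")
  cl <- labeller$node_class[nearest_node(Xs, labeller$codes)]
  if (is_arr) matrix(cl, dm[1], dm[2]) else cl
}

#' Segment the live-coral region of a frame
#'
#' Pixel-labelling segmentation: Gabor features, SOM nearest-prototype
#' classification, then morphological opening and closing to suppress
#' salt-and-pepper labels.
#'
#' @param frame a [reef_frame()] (or a precomputed `h x w x d` feature
#'   array matching the labeller's bank).
#' @param labeller a trained [train_pixel_labeller()] whose positive class
#'   is `coral_class`.
#' @param coral_class label treated as live coral.
#' @param clean_radius disc radius (pixels) of the morphological clean-up;
#'   0 disables it.
#' @return logical `height x width` coral mask.
#' @export
segment_coral <- function(frame, labeller, coral_class = "coral",
                          clean_radius = 2) {
  feats <- if (inherits(frame, "reef_frame"))
    extract_gabor_features(frame, labeller$bank) else frame
  cl <- predict_pixels(labeller, feats)
  mask <- cl == coral_class
  if (clean_radius > 0) {
    brush <- EBImage::makeBrush(2L * clean_radius + 1L, shape = "disc")
    img <- EBImage::Image(mask * 1)
    img <- EBImage::closing(EBImage::opening(img, brush), brush)
    mask <- as.matrix(img) > 0.5
  }
  mask
}
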