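# Patch classifier: a small convolutional network with the classic
# LeNet-5 layout adapted to 46x46x3 colour patches — two conv(5x5) +
# average-pool(2x2) blocks, one hidden dense layer, softmax output.
# Implemented with im2col gathers and BLAS matrix products; trained by
# minibatch SGD with momentum on the softmax cross-entropy.
#
# Layout conventions: a batch is an n x D matrix whose rows are vectorized
# (h, w, c) arrays (column-major: y fastest, then x, then channel); conv
# and pool stages keep the (position-fastest, then feature-map) ordering
# so the same gather machinery serves every stage.

# im2col gather indices: for each output position, the vector indices of
# its k x k x C receptive field in the (h, w, C) input.
im2col_index <- function(h, w, C, k) {
  ho <- h - k + 1L; wo <- w - k + 1L
  pos <- expand.grid(yo = seq_len(ho), xo = seq_len(wo))
  fld <- expand.grid(dy = 0:(k - 1L), dx = 0:(k - 1L), c = 0:(C - 1L))
  idx <- matrix(0L, nrow(pos), nrow(fld))
  for (e in seq_len(nrow(fld))) {
    idx[, e] <- (pos$yo + fld$dy[e]) + h * (pos$xo + fld$dx[e] - 1L) +
      h * w * fld$c[e]
  }
  list(idx = idx, ho = ho, wo = wo)
}

# 2x2 average-pool gather indices over an (h, w, F) input (odd trailing
# row/column cropped).
pool_index <- function(h, w, F) {
  ho <- h %/% 2L; wo <- w %/% 2L
  pos <- expand.grid(yo = seq_len(ho), xo = seq_len(wo), f = seq_len(F))
  base <- (2L * pos$yo - 1L) + h * (2L * pos$xo - 2L) + h * w * (pos$f - 1L)
  idx <- cbind(base, base + 1L, base + h, base + h + 1L)
  list(idx = idx, ho = ho, wo = wo)
}

gather <- function(X, idx) {
  n <- nrow(X)
  Y <- X[, as.vector(idx), drop = FALSE]
  dim(Y) <- c(n * nrow(idx), ncol(idx))
  Y
}

scatter_add <- function(dX, dCol, idx, n) {
  P <- nrow(idx)
  dim(dCol) <- c(n, P * ncol(idx))
  for (e in seq_len(ncol(idx))) {
    cols <- idx[, e]
    dX[, cols] <- dX[, cols] + dCol[, (e - 1L) * P + seq_len(P)]
  }
  dX
}

#' Training specification for the patch classifier
#'
#' @param epochs training epochs.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay per epoch.
#' @param momentum SGD momentum.
#' @param batch minibatch size.
#' @param conv1,conv2 number of feature maps in the two conv blocks.
#' @param kernel conv kernel edge (5, the LeNet choice).
#' @param hidden units of the dense hidden layer.
#' @return list of class `lenet_spec`.
#' @export
lenet_spec <- function(epochs = 10, lr = 0.01, lr_decay = 0.95,
                       momentum = 0.9, batch = 64L, conv1 = 6L, conv2 = 16L,
                       kernel = 5L, hidden = 84L) {
  structure(as.list(environment()), class = "lenet_spec")
}

# Build the network geometry and initial weights for a given input size.
lenet_init <- function(size, channels, n_classes, spec, seed) {
  k <- spec$kernel
  g1 <- im2col_index(size, size, channels, k)
  p1 <- pool_index(g1$ho, g1$wo, spec$conv1)
  g2 <- im2col_index(p1$ho, p1$wo, spec$conv1, k)
  p2 <- pool_index(g2$ho, g2$wo, spec$conv2)
  d_flat <- p2$ho * p2$wo * spec$conv2
  if (d_flat < 1L) rp_stop("patch size %d too small for this layout", size)
  set.seed(seed)
  he <- function(fan_in, n) matrix(rnorm(fan_in * n, sd = sqrt(2 / fan_in)),
                                   fan_in, n)
  list(g1 = g1, p1 = p1, g2 = g2, p2 = p2, d_flat = d_flat,
       W1 = he(k * k * channels, spec$conv1), b1 = rep(0, spec$conv1),
       W2 = he(k * k * spec$conv1, spec$conv2), b2 = rep(0, spec$conv2),
       W3 = he(d_flat, spec$hidden), b3 = rep(0, spec$hidden),
       W4 = he(spec$hidden, n_classes), b4 = rep(0, n_classes))
}

# Forward pass; returns softmax probabilities and (optionally) the
# intermediate activations needed for the backward pass.
lenet_forward <- function(net, X, keep = FALSE) {
  n <- nrow(X)
  C1 <- gather(X, net$g1$idx)
  Z1 <- sweep(C1 %*% net$W1, 2, net$b1, `+`)
  A1 <- pmax(Z1, 0)
  A1m <- A1; dim(A1m) <- c(n, nrow(net$g1$idx) * ncol(net$W1))
  P1g <- gather(A1m, net$p1$idx)
  P1 <- rowMeans(P1g); dim(P1) <- c(n, nrow(net$p1$idx))
  C2 <- gather(P1, net$g2$idx)
  Z2 <- sweep(C2 %*% net$W2, 2, net$b2, `+`)
  A2 <- pmax(Z2, 0)
  A2m <- A2; dim(A2m) <- c(n, nrow(net$g2$idx) * ncol(net$W2))
  P2g <- gather(A2m, net$p2$idx)
  P2 <- rowMeans(P2g); dim(P2) <- c(n, nrow(net$p2$idx))
  Z3 <- sweep(P2 %*% net$W3, 2, net$b3, `+`)
  A3 <- pmax(Z3, 0)
  Z4 <- sweep(A3 %*% net$W4, 2, net$b4, `+`)
  Z4 <- Z4 - apply(Z4, 1, max)
  E <- exp(Z4)
  probs <- E / rowSums(E)
  if (!keep) return(list(probs = probs))
  list(probs = probs, X = X, C1 = C1, A1 = A1, A1m = A1m, P1 = P1,
       C2 = C2, A2 = A2, A2m = A2m, P2 = P2, A3 = A3)
}

# Backward pass from softmax cross-entropy; returns gradients.
lenet_backward <- function(net, fwd, y_onehot) {
  n <- nrow(fwd$X)
  dZ4 <- (fwd$probs - y_onehot) / n
  gW4 <- crossprod(fwd$A3, dZ4); gb4 <- colSums(dZ4)
  dA3 <- tcrossprod(dZ4, net$W4) * (fwd$A3 > 0)
  gW3 <- crossprod(fwd$P2, dA3); gb3 <- colSums(dA3)
  dP2 <- tcrossprod(dA3, net$W3)
  # pool2 backward: spread gradient equally over the 4 pooled inputs
  dA2m <- matrix(0, n, ncol(fwd$A2m))
  dA2m <- scatter_add(dA2m, matrix(rep(as.vector(dP2) / 4, 4),
                                   n * nrow(net$p2$idx), 4), net$p2$idx, n)
  dZ2 <- dA2m; dim(dZ2) <- c(n * nrow(net$g2$idx), ncol(net$W2))
  dZ2 <- dZ2 * (fwd$A2 > 0)
  gW2 <- crossprod(fwd$C2, dZ2); gb2 <- colSums(dZ2)
  dC2 <- tcrossprod(dZ2, net$W2)
  dP1 <- matrix(0, n, ncol(fwd$P1))
  dP1 <- scatter_add(dP1, dC2, net$g2$idx, n)
  dA1m <- matrix(0, n, ncol(fwd$A1m))
  dA1m <- scatter_add(dA1m, matrix(rep(as.vector(dP1) / 4, 4),
                                   n * nrow(net$p1$idx), 4), net$p1$idx, n)
  dZ1 <- dA1m; dim(dZ1) <- c(n * nrow(net$g1$idx), ncol(net$W1))
  dZ1 <- dZ1 * (fwd$A1 > 0)
  gW1 <- crossprod(fwd$C1, dZ1); gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Train the patch classifier
#'
#' Trains the LeNet-style network on the `train` split of a labelled,
#' split patch set, monitoring the `val` split, and reports per-split
#' accuracy (including `test`).  Training is deterministic under a fixed
#' seed.
#'
#' @param ps a [patch_set()] with labels and splits (see
#'   [split_dataset()]).
#' @param spec a [lenet_spec()].
#' @param seed RNG seed (weight init and batch shuffling).
#' @param positive_class class whose softmax probability is reported as
#'   the activity likelihood (`"active"`).
#' @param verbose print per-epoch progress.
#' @return object of class `polyp_classifier` with the trained weights,
#'   class levels, and `accuracy` (named per-split vector).
#' @export
train_classifier <- function(ps, spec = lenet_spec(), seed = 1,
                             positive_class = "active", verbose = FALSE) {
  stopifnot(inherits(ps, "patch_set"), inherits(spec, "lenet_spec"))
  if (anyNA(ps$meta$split))
    rp_stop("patch set has unassigned splits; run split_dataset() first")
  if (anyNA(ps$meta$label)) rp_stop("patch set has unlabelled patches")
  classes <- sort(unique(ps$meta$label))
  tr <- ps$meta$split == "train"; va <- ps$meta$split == "val"
  if (!any(tr) || !any(va)) rp_stop("train and val splits must be non-empty")
  if (!all(classes %in% unique(ps$meta$label[tr])))
    rp_stop("class missing from the training split")

  y <- match(ps$meta$label, classes)
  mu <- colMeans(ps$patches[tr, , drop = FALSE])
  net <- lenet_init(ps$size, 3L, length(classes), spec, seed)
  vel <- lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                function(w) w * 0)
  itr <- which(tr)
  lr <- spec$lr
  set.seed(seed + 1L)
  for (ep in seq_len(spec$epochs)) {
    ord <- sample(itr)
    for (b0 in seq(1L, length(ord), by = spec$batch)) {
      bi <- ord[b0:min(b0 + spec$batch - 1L, length(ord))]
      X <- sweep(ps$patches[bi, , drop = FALSE], 2, mu)
      oh <- matrix(0, length(bi), length(classes))
      oh[cbind(seq_along(bi), y[bi])] <- 1
      fwd <- lenet_forward(net, X, keep = TRUE)
      gr <- lenet_backward(net, fwd, oh)
      for (nm in names(gr)) {
        vel[[nm]] <- spec$momentum * vel[[nm]] - lr * gr[[nm]]
        net[[nm]] <- net[[nm]] + vel[[nm]]
      }
    }
    lr <- lr * spec$lr_decay
    if (verbose) {
      acc <- classifier_accuracy_internal(net, mu, classes, ps, va, spec$batch)
      message(sprintf("epoch %d: val accuracy %.3f", ep, acc))
    }
  }
  clf <- structure(list(net = net, mu = mu, classes = classes,
                        size = ps$size, positive_class = positive_class,
                        spec = spec, seed = seed),
                   class = "polyp_classifier")
  acc <- vapply(c(train = "train", val = "val", test = "test"), function(s) {
    i <- ps$meta$split == s
    if (!any(i)) return(NA_real_)
    mean(predict_classifier(clf, ps$patches[i, , drop = FALSE],
                            type = "class") == ps$meta$label[i])
  }, numeric(1))
  clf$accuracy <- acc
  clf
}

classifier_accuracy_internal <- function(net, mu, classes, ps, which_i, batch) {
  idx <- which(which_i)
  hit <- 0L
  for (b0 in seq(1L, length(idx), by = batch)) {
    bi <- idx[b0:min(b0 + batch - 1L, length(idx))]
    X <- sweep(ps$patches[bi, , drop = FALSE], 2, mu)
    p <- lenet_forward(net, X)$probs
    hit <- hit + sum(classes[max.col(p)] == ps$meta$label[bi])
  }
  hit / length(idx)
}

#' @export
print.polyp_classifier <- function(x, ...) {
  cat(sprintf("<polyp_classifier> %dx%d input, classes: %s\n",
              x$size, x$size, paste(x$classes, collapse = ", ")))
  if (!is.null(x$accuracy))
    cat(sprintf("  accuracy: %s\n",
                paste(sprintf("%s=%.3f", names(x$accuracy), x$accuracy),
                      collapse = " ")))
  invisible(x)
}

#' Classifier predictions for patches
#'
#' @param clf a `polyp_classifier`.
#' @param patches a [patch_set()] or an `n x (size^2*3)` matrix.
#' @param type `"likelihood"` (probability of the positive class, in
#'   \[0, 1\]), `"prob"` (full softmax matrix) or `"class"`.
#' @param batch evaluation batch size.
#' @return numeric vector, matrix, or character vector accordingly.
#' @export
predict_classifier <- function(clf, patches, type = c("likelihood", "prob",
                                                      "class"),
                               batch = 96L) {
  type <- match.arg(type)
  X <- if (inherits(patches, "patch_set")) patches$patches else patches
  n <- nrow(X)
  probs <- matrix(NA_real_, n, length(clf$classes))
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, n)
    probs[bi, ] <- lenet_forward(clf$net,
                                 sweep(X[bi, , drop = FALSE], 2, clf$mu))$probs
  }
  colnames(probs) <- clf$classes
  switch(type,
         prob = probs,
         class = clf$classes[max.col(probs, ties.method = "first")],
         likelihood = {
           if (clf$positive_class %in% clf$classes)
             probs[, clf$positive_class]
           else rep(0, n)
         })
}

#' Save / load a classifier as plain text (JSON)
#'
#' Weights and metadata are serialized to JSON so checkpoints stay
#' text-only and portable.
#'
#' @param clf a `polyp_classifier`.
#' @param path output file.
#' @export
write_classifier <- function(clf, path) {
  net <- clf$net
  payload <- list(
    classes = clf$classes, size = clf$size, mu = clf$mu,
    positive_class = clf$positive_class, seed = clf$seed,
    accuracy = as.list(clf$accuracy),
    spec = unclass(clf$spec),
    weights = lapply(net[c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")],
                     function(w) if (is.matrix(w))
                       list(dim = dim(w), x = as.vector(w))
                     else list(dim = length(w), x = as.vector(w))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(lenet_spec, as.list(p$spec))
  net <- lenet_init(p$size, 3L, length(p$classes), spec, seed = p$seed)
  for (nm in names(p$weights)) {
    w <- p$weights[[nm]]
    net[[nm]] <- if (length(w$dim) == 2L) matrix(w$x, w$dim[1], w$dim[2])
                 else as.numeric(w$x)
  }
  acc <- unlist(p$accuracy)
  structure(list(net = net, mu = as.numeric(p$mu), classes = p$classes,
                 size = p$size, positive_class = p$positive_class,
                 spec = spec, seed = p$seed, accuracy = acc),
            class = "polyp_classifier")
}
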