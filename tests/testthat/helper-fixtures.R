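# Shared small fixtures, built in code at test time.

# A small rendered scene reused by several image-side tests.
fixture_scene <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      region <- make_coral_region(256, 256, coverage = 0.5, seed = 3)
      cache <<- list(
        region = region,
        truth = scene_truth(region, redness_a = 8),
        frame = generate_reef_frame(scene_truth(region, redness_a = 8),
                                    seed = 5))
    }
    cache
  }
})

# A labeller trained on the fixture scene's true region.
fixture_labeller <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_scene()
      feats <- extract_gabor_features(fx$frame)
      lab <- rep(NA_character_, length(fx$region))
      set.seed(2)
      idx <- sample(length(fx$region), 6000)
      lab[idx] <- ifelse(fx$region[idx], "coral", "background")
      cache <<- train_pixel_labeller(feature_matrix(feats), lab, seed = 4)
    }
    cache
  }
})

# A small patch set of the three synthetic classes (active star / inactive
# disc / background texture), unaugmented.
fixture_patches <- function(n_frames = 3, n_polyps = 8, seed = 21,
                            width = 320, height = 320) {
  seqd <- generate_sequence(n_frames, color_trajectory = 6,
                            activity_trajectory = 0.5, jitter_sd = 0,
                            missing_fraction = 0, seed = seed,
                            width = width, height = height,
                            n_polyps = n_polyps)
  anns <- generate_annotations(seqd$truths, seed = seed + 1)
  sets <- list(); off <- 0L
  for (i in seq_along(seqd$frames)) {
    ai <- anns[anns$image == seqd$truths[[i]]$id, ]
    sets[[i]] <- extract_patches(seqd$frames[[i]], ai, source_offset = off)
    off <- off + nrow(ai)
  }
  mask <- build_polyp_mask(anns[anns$image == seqd$truths[[1]]$id, ],
                           dim(seqd$frames[[1]]$data)[1:2])
  bg <- sample_background(seqd$frames[[1]], mask, n = 20, seed = seed + 2,
                          source_offset = off)
  list(patches = do.call(bind_patches, c(sets, list(bg))),
       sequence = seqd, annotations = anns, mask = mask)
}

# Degenerate but genuine classifier: all weights zero, output bias fixed,
# so every patch gets the same softmax output through the real forward
# pass (classes sorted: active, inactive).
stub_classifier <- function(active = TRUE, size = 46L) {
  spec <- lenet_spec()
  net <- reefpulse:::lenet_init(size, 3L, 2L, spec, seed = 1)
  for (nm in c("W1", "W2", "W3", "W4")) net[[nm]][] <- 0
  net$b4 <- if (active) c(20, -20) else c(-20, 20)
  structure(list(net = net, mu = rep(0, size * size * 3),
                 classes = c("active", "inactive"), size = size,
                 positive_class = "active", spec = spec, seed = 1,
                 accuracy = NULL),
            class = "polyp_classifier")
}
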