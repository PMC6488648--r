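# Polyp masks, patches, augmentation, splits, activity and agreement.

test_that("polyp mask is the clipped union of discs", {
  # radius 1: the minimal 4-neighbour disc of 5 pixels
  a <- data.frame(image = 1, x = 5, y = 5, class = "active", annotator = "A")
  m <- build_polyp_mask(a, c(9, 9), disc_radius = 1)
  expect_equal(sum(m), 5)
  expect_true(m[5, 5] && m[4, 5] && m[6, 5] && m[5, 4] && m[5, 6])

  # overlapping points: union, no double counting
  b <- rbind(a, transform(a, x = 6))
  m2 <- build_polyp_mask(b, c(9, 9), disc_radius = 1)
  expect_equal(sum(m2), 8)

  # a point on the border stays clipped to the raster / ROI
  c1 <- data.frame(image = 1, x = 1, y = 1, class = "inactive",
                   annotator = "A")
  m3 <- build_polyp_mask(c1, c(9, 9), disc_radius = 2)
  expect_equal(dim(m3), c(9, 9))
  roi <- matrix(FALSE, 9, 9); roi[1:3, 1:3] <- TRUE
  m4 <- build_polyp_mask(c1, roi, disc_radius = 5)
  expect_true(all(which(m4) %in% which(roi)))

  expect_error(build_polyp_mask(a[0, ], c(9, 9)), "empty")
})

test_that("patch extraction crops exactly and skips infeasible centres", {
  set.seed(4)
  f <- reef_frame(array(runif(100 * 100 * 3), c(100, 100, 3)))
  ps <- extract_patches(f, data.frame(x = 50, y = 50, class = "active"))
  expect_equal(n_patches(ps), 1)
  expect_equal(patch_array(ps, 1), f$data[28:73, 28:73, ])

  # 10 px from the border: no room for a 46 px patch -> skipped and logged
  ps2 <- extract_patches(f, data.frame(x = c(10, 50), y = c(50, 50),
                                       class = c("active", "inactive")))
  expect_equal(n_patches(ps2), 1)
  expect_equal(attr(ps2, "skipped"), 1L)

  centres <- data.frame(x = c(30, 50, 70), y = c(30, 50, 70),
                        class = "active")
  expect_equal(n_patches(extract_patches(f, centres)), 3)
})

test_that("background sampling avoids the mask and fails loudly on shortage", {
  set.seed(9)
  f <- reef_frame(array(runif(120 * 120 * 3), c(120, 120, 3)))
  mask <- matrix(FALSE, 120, 120); mask[40:80, 40:80] <- TRUE
  bg <- sample_background(f, mask, n = 50, seed = 2)
  expect_equal(n_patches(bg), 50)
  expect_true(all(!mask[cbind(bg$meta$cy, bg$meta$cx)]))
  expect_true(all(bg$meta$label == "background"))
  # the documented default background count
  expect_equal(formals(sample_background)$n, 100L)

  full <- matrix(TRUE, 120, 120)
  full[60, 60] <- FALSE
  one <- sample_background(f, full, n = 1, seed = 3)
  expect_equal(c(one$meta$cx, one$meta$cy), c(60, 60))
  expect_error(sample_background(f, full, n = 2, seed = 3), "feasible")
})

test_that("augmentation multiplies any patch set by exactly 48", {
  fx <- fixture_patches(n_frames = 1, n_polyps = 6, seed = 41)
  ps <- fx$patches
  for (n_in in c(1, 5)) {
    sub <- patch_set(ps$patches[seq_len(n_in), , drop = FALSE],
                     ps$meta[seq_len(n_in), ], ps$size)
    out <- augment_patches(sub, seed = 1)
    expect_equal(n_patches(out), 48 * n_in)
    # provenance: every output descends from an input source
    expect_true(all(out$meta$source_id %in% sub$meta$source_id))
    expect_equal(length(unique(out$meta$aug_op)), 48)
  }
  empty <- patch_set(ps$patches[0, , drop = FALSE], ps$meta[0, ], ps$size)
  expect_equal(n_patches(augment_patches(empty)), 0)

  # the identity operation is among the 48 outputs, bit-exact
  one <- patch_set(ps$patches[1, , drop = FALSE], ps$meta[1, ], ps$size)
  out1 <- augment_patches(one, seed = 1)
  id_row <- which(out1$meta$aug_op == "id_rot000")
  expect_equal(out1$patches[id_row, ], ps$patches[1, ])
})

test_that("splits are assigned per source with the exact 70/20/10 counts", {
  size <- 8L
  n_src <- 100L
  set.seed(12)
  ps <- patch_set(matrix(runif(n_src * size * size * 3), n_src),
                  data.frame(label = rep(c("active", "inactive"), 50),
                             split = NA_character_, source_id = 1:n_src,
                             image = 1, cx = 1, cy = 1, aug_op = "orig"),
                  size)
  aug <- augment_patches(ps, seed = 2)
  sp <- split_dataset(aug, seed = 3)
  per_src <- unique(sp$meta[, c("source_id", "split")])
  expect_equal(nrow(per_src), n_src)   # every source has exactly one split
  expect_equal(unname(table(per_src$split)[c("train", "val", "test")]),
               c(70L, 20L, 10L), ignore_attr = TRUE)

  # no augmented descendant of a val/test source reaches the training set
  leak <- merge(sp$meta, per_src, by = "source_id")
  expect_true(all(leak$split.x == leak$split.y))

  # deterministic under the seed
  sp2 <- split_dataset(aug, seed = 3)
  expect_identical(sp$meta$split, sp2$meta$split)
  expect_error(split_dataset(aug, fractions = c(0.9, 0.2, -0.1)), "sum to 1")
})

test_that("polyp activity is the exact masked active fraction", {
  mask <- matrix(TRUE, 10, 10)
  all_on <- matrix(TRUE, 10, 10)
  expect_equal(as.numeric(polyp_activity(all_on, mask)), 1)
  expect_equal(as.numeric(polyp_activity(!all_on, mask)), 0)

  set.seed(2)
  act <- matrix(FALSE, 10, 10)
  act[sample(100, 37)] <- TRUE
  expect_equal(as.numeric(polyp_activity(act, mask)), 0.37)
  expect_error(polyp_activity(act, matrix(FALSE, 10, 10)), "empty")
})

test_that("pixel classification respects the mask and matches brute force", {
  set.seed(7)
  clf <- stub_classifier(active = TRUE)
  f <- reef_frame(array(runif(140 * 140 * 3), c(140, 140, 3)))
  mask <- matrix(FALSE, 140, 140)
  mask[60:80, 60:80] <- TRUE
  res <- classify_pixels(f, mask, clf, stride = 1)
  expect_true(all(res$active[mask]))
  expect_true(all(is.na(res$likelihood[!mask])))
  expect_equal(res$n_skipped, 0)
  expect_equal(as.numeric(polyp_activity(res$active, mask)), 1)

  # a genuine (random-weight) network: stride 1 equals the per-pixel loop
  rnd <- stub_classifier(active = TRUE)
  set.seed(31)
  for (nm in c("W1", "W2", "W3", "W4"))
    rnd$net[[nm]][] <- rnorm(length(rnd$net[[nm]]), sd = 0.05)
  rnd$net$b4 <- c(0, 0)
  small_mask <- matrix(FALSE, 140, 140)
  small_mask[69:72, 69:72] <- TRUE
  r1 <- classify_pixels(f, small_mask, rnd, stride = 1)
  px <- which(small_mask, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    p <- extract_patches(f, data.frame(x = px[i, 2], y = px[i, 1]))
    lik <- predict_classifier(rnd, p, type = "likelihood")
    expect_equal(r1$likelihood[px[i, 1], px[i, 2]], unname(lik),
                 tolerance = 1e-12)
  }

  # stride > 1 nearest-fill stays close to the exact map on gamma
  r2 <- classify_pixels(f, small_mask, rnd, stride = 2)
  g1 <- polyp_activity(r1$active, small_mask)
  g2 <- polyp_activity(r2$active, small_mask)
  expect_lt(abs(as.numeric(g1) - as.numeric(g2)), 0.25)
})

test_that("observer agreement follows the matched-pair formula", {
  mk <- function(x, y, cls, ann = "A")
    data.frame(image = 1, x = x, y = y, class = cls, annotator = ann)
  a <- mk(seq(10, 100, by = 10), 50, rep(c("active", "inactive"), 5))
  expect_equal(as.numeric(observer_agreement(a, a)), 1)

  b_far <- mk(seq(10, 100, by = 10), 500, a$class, "B")
  expect_equal(as.numeric(observer_agreement(a, b_far, match_radius = 23)), 0)

  # 10 matched pairs, 8 with equal class, none unmatched -> 0.8
  b <- a; b$x <- b$x + 2
  b$class[1:2] <- rev(c("active", "inactive"))[match(b$class[1:2],
                                                     c("active", "inactive"))]
  ag <- observer_agreement(a, b, match_radius = 23)
  expect_equal(attr(ag, "n_matched"), 10L)
  expect_equal(as.numeric(ag), 0.8)

  # unmatched extra points count against agreement
  b_extra <- rbind(b, mk(200, 200, "active", "B"))
  ag2 <- observer_agreement(a, b_extra, match_radius = 23)
  expect_equal(as.numeric(ag2), 8 / 11)
  expect_error(observer_agreement(a[0, ], a[0, ]), "empty")
})

test_that("manual activity is the count-based active fraction", {
  a <- data.frame(image = 1, x = 1:12 * 10, y = 50,
                  class = c(rep("active", 3), rep("inactive", 9)),
                  annotator = "A")
  expect_equal(manual_gamma(a), 0.25)
  expect_equal(manual_gamma(transform(a, class = "active")), 1)
  mask <- matrix(FALSE, 100, 200); mask[, 1:60] <- TRUE
  expect_equal(manual_gamma(a, mask), mean(a$class[1:6] == "active"))
})
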