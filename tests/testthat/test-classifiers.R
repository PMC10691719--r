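# classifier tests run on small phantoms so the whole file stays fast;
# scales above half the image side are dropped by design, so the feature
# bank warning is expected and silenced via suppressWarnings

small_spec <- function(seed, n = 128L, fibres = 3L) {
  phantom_spec(image_size_px = n, n_fibres = fibres,
               axon_radius = list(meanlog = log(11), sdlog = 0.15,
                                  min = 9, max = 16),
               seed = seed)
}

test_that("axoplasm candidate extraction applies threshold, size filter and numbering", {
  d <- c(30, 30)
  p <- array(0, c(d, 3)); p[, , 2] <- 0.5; p[, , 3] <- 0.5
  expect_equal(max(axoplasm_candidates(prob_stack(p), smooth_sigma = 0)$labels),
               0)  # uniform 0.5 axoplasm: below threshold

  # one 100-px blob at 0.9 on 0 background
  p <- array(0, c(d, 3)); p[, , 3] <- 1
  blob <- as.matrix(expand.grid(6:15, 6:15))
  for (i in seq_len(nrow(blob))) {
    p[blob[i, 1], blob[i, 2], 2] <- 0.9
    p[blob[i, 1], blob[i, 2], 3] <- 0.1
  }
  cand <- axoplasm_candidates(prob_stack(p), smooth_sigma = 0)
  expect_equal(max(cand$labels), 1)
  expect_equal(sum(cand$labels == 1L), 100)

  # 9-px and 12-px blobs: only the 12-px blob survives the size filter
  p <- array(0, c(d, 3)); p[, , 3] <- 1
  set9 <- cbind(rep(3:5, 3), rep(3:5, each = 3))
  set12 <- cbind(rep(20:23, 3), rep(20:22, each = 4))
  for (i in seq_len(9)) { p[set9[i, 1], set9[i, 2], 2] <- 1; p[set9[i, 1], set9[i, 2], 3] <- 0 }
  for (i in seq_len(12)) { p[set12[i, 1], set12[i, 2], 2] <- 1; p[set12[i, 1], set12[i, 2], 3] <- 0 }
  cand <- axoplasm_candidates(prob_stack(p), smooth_sigma = 0, min_size_px = 10)
  expect_equal(max(cand$labels), 1)
  expect_equal(sum(cand$labels > 0L), 12)
})

test_that("raising min_size_px never adds instances (monotonicity)", {
  ph <- generate_phantom(small_spec(31))
  counts <- vapply(c(1, 10, 50, 200, 1000), function(ms) {
    max(axoplasm_candidates(ph$ideal_probs, min_size_px = ms)$labels)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("object features capture shape and intensity as specified", {
  n <- 30
  sq <- as.vector(outer(10:20, (10:20 - 1) * n, "+"))   # solid 11x11 square
  lab <- matrix(0L, n, n); lab[sq] <- 1L
  img <- image2d(matrix(0.4, n, n), 1)
  ft <- object_feature_table(instance_map(lab, "axon"), img)
  expect_equal(ft$area, 121)
  expect_equal(ft$extent, 1)
  expect_equal(ft$int_mean, 0.4)
  expect_equal(ft$int_sd, 0)

  # disk vs same-area elongated ellipse: eccentricity orders them
  disk <- disc_pixels(60, 20, 20, 10)
  cc <- matrix(rep(1:60, each = 60), 60); rr <- matrix(rep(1:60, 60), 60)
  ell <- which(((rr - 40) / 20)^2 + ((cc - 40) / 5)^2 <= 1)
  lab2 <- matrix(0L, 60, 60); lab2[disk] <- 1L; lab2[ell] <- 2L
  ft2 <- object_feature_table(instance_map(lab2, "axon"),
                              image2d(matrix(0.5, 60, 60), 1))
  expect_lt(ft2$eccentricity[1], ft2$eccentricity[2])
  expect_false(any(c("cx", "cy", "centroid") %in% names(ft2)))
})

test_that("autocontext training is deterministic and separates phantom classes", {
  # blur-free phantom: class intensities are cleanly separable, so the
  # stage-A forest should be near-perfect out of bag (> 0.95 accuracy)
  ph <- generate_phantom(phantom_spec(
    image_size_px = 192L, n_fibres = 5L,
    axon_radius = list(meanlog = log(11), sdlog = 0.15, min = 9, max = 16),
    blur_sigma_px = 0, seed = 7L))
  scrib <- sample_scribbles(ph, n_per_class = 150L, seed = 2L)
  codes <- unique(scrib[scrib > 0L])
  expect_true(all(1:3 %in% codes) && all(codes %in% 1:4))
  m1 <- suppressWarnings(
    train_pixel_autocontext(ph$image, scrib, seed = 5L, num_trees = 60L))
  m2 <- suppressWarnings(
    train_pixel_autocontext(ph$image, scrib, seed = 5L, num_trees = 60L))
  probe <- generate_phantom(small_spec(8))
  p1 <- suppressWarnings(predict_probabilities(m1, probe$image))
  p2 <- suppressWarnings(predict_probabilities(m2, probe$image))
  expect_identical(p1$p, p2$p)                      # bit-identical predictions
  expect_lt(m1$oob_error_a, 0.05)                   # separable intensities
  # per-pixel probabilities: valid simplex
  sums <- p1$p[, , 1] + p1$p[, , 2] + p1$p[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(p1$p >= 0 & p1$p <= 1))
  # deep inside a myelin ring the argmax channel is myelin
  ring <- which(probe$gt_semantic$labels == 3L)
  er <- ring[order(probe$ideal_probs$p[, , 1][ring], decreasing = TRUE)[1:50]]
  cls <- argmax_channel(p1)
  expect_gt(mean(cls[er] == 1L), 0.9)
})

test_that("stage B always has 3 classes and missing scribble classes are named", {
  ph <- generate_phantom(small_spec(11))
  scrib <- sample_scribbles(ph, n_per_class = 50L, seed = 3L)
  model <- suppressWarnings(
    train_pixel_autocontext(ph$image, scrib, seed = 1L, num_trees = 40L))
  expect_equal(model$classes_b, c("compact_myelin", "axoplasm", "membrane"))

  scrib2 <- scrib
  scrib2[scrib2 == 3L] <- 0L
  expect_error(
    suppressWarnings(train_pixel_autocontext(ph$image, scrib2, seed = 1L)),
    "membrane")
})

test_that("object classifier separates crescents from disks and is deterministic", {
  ph_tr <- generate_phantom(small_spec(21, n = 160L, fibres = 5L))
  tr <- phantom_object_training(ph_tr)
  ok <- !is.na(tr$features$true_class)
  expect_gt(sum(ok), 3)
  om1 <- train_object_classifier(tr$features[ok, ], tr$features$true_class[ok],
                                 seed = 4L)
  om2 <- train_object_classifier(tr$features[ok, ], tr$features$true_class[ok],
                                 seed = 4L)
  ph_te <- generate_phantom(small_spec(22, n = 160L, fibres = 5L))
  te <- phantom_object_training(ph_te)
  c1 <- classify_objects(om1, te$features)
  c2 <- classify_objects(om2, te$features)
  expect_identical(c1$predicted_class, c2$predicted_class)
  # held-out crescents recognised as inner tongue, disks as axons
  known <- !is.na(te$features$true_class)
  is_tongue_true <- te$features$true_class[known] == "inner_tongue"
  is_tongue_pred <- c1$predicted_class[known] == "inner_tongue"
  expect_gt(mean(is_tongue_true == is_tongue_pred), 0.7)
  # empty candidate list passes through
  empty <- classify_objects(om1, object_feature_table(
    instance_map(matrix(0L, 10, 10), "axon"), image2d(matrix(0.5, 10, 10), 1)))
  expect_equal(nrow(empty), 0)
})
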