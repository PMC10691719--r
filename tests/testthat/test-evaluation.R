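test_that("IoU counts pixels as specified", {
  a <- 1:4; b <- 3:8
  expect_equal(iou(a, a), 1)
  expect_equal(iou(1:4, 11:14), 0)
  expect_equal(iou(1:4, c(3, 4, 21, 22)), 2 / 6)
  expect_error(iou(integer(), integer()), "empty")
})

test_that("matching identical maps is perfect at every threshold", {
  maps <- random_toy_maps(5)
  for (th in c(0.5, 0.7, 0.9)) {
    m <- match_instances(maps$target, maps$target, th)
    expect_equal(m$FP, 0); expect_equal(m$FN, 0)
    expect_equal(m$TP, m$n_target)
  }
  expect_error(match_instances(maps$target, maps$prediction, 0.4), "0.5")
})

test_that("a missing object costs one FN and no FP", {
  n <- 30
  t <- matrix(0L, n, n)
  for (i in 1:5) t[disc_pixels(n, 5 * i, 15, 2)] <- i
  p <- t; p[p == 3L] <- 0L
  m <- match_instances(instance_map(t, "fibre"), instance_map(p, "fibre"), 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(4, 0, 1))
})

test_that("greedy matching equals exhaustive optimal assignment", {
  skip_if_not_installed("igraph")   # suite-level guard irrelevant; cheap anyway
  for (seed in 1:25) {
    maps <- random_toy_maps(seed)
    m <- match_instances(maps$target, maps$prediction, 0.5)
    bf <- brute_force_match(maps$target$labels, maps$prediction$labels, 0.5)
    expect_equal(m$TP, bf$n)
    if (m$TP > 0) {
      expect_equal(dplyr::arrange(m$pairs, target),
                   dplyr::arrange(bf$pairs, target), tolerance = 1e-12)
    }
  }
})

test_that("detection scores reproduce the precision/recall/F1 identities", {
  n <- 60
  t <- matrix(0L, n, n)
  k <- 0L
  for (r in seq(5, 55, by = 10)) for (c in c(15, 45)) {
    k <- k + 1L
    t[disc_pixels(n, c, r, 3)] <- k
  }                                              # 12 targets
  t[t > 10L] <- 0L                               # keep 10
  p <- t
  p[p %in% c(9L, 10L)] <- 0L                     # miss two -> FN 2
  p[disc_pixels(n, 30, 3, 2)] <- 11L             # two spurious -> FP 2
  p[disc_pixels(n, 33, 57, 2)] <- 12L
  sc <- detection_scores(instance_map(t, "fibre"), instance_map(p, "fibre"),
                         thresholds = 0.5)
  expect_equal(sc$per_threshold$precision, 0.8)
  expect_equal(sc$per_threshold$recall, 0.8)
  expect_equal(sc$per_threshold$f1, 0.8)

  perfect <- detection_scores(instance_map(t, "fibre"), instance_map(t, "fibre"))
  expect_equal(perfect$avg_f1, 1); expect_equal(perfect$mean_jaccard, 1)
})

test_that("uniform 60% erosion flips F1 from 1 to 0 across the threshold range", {
  n <- 60
  t <- matrix(0L, n, n); p <- matrix(0L, n, n)
  k <- 0L
  for (r in c(10, 30, 50)) for (c in c(15, 45)) {
    k <- k + 1L
    px <- sort(disc_pixels(n, c, r, 4))
    t[px] <- k
    p[px[seq_len(ceiling(0.6 * length(px)))]] <- k   # subset, IoU = 0.6
  }
  sc <- detection_scores(instance_map(t, "fibre"), instance_map(p, "fibre"))
  per <- sc$per_threshold
  expect_true(all(per$f1[per$threshold <= 0.6] == 1))
  expect_true(all(per$f1[per$threshold >= 0.65] == 0))
  expect_equal(sc$avg_f1, 3 / 9)
  expect_equal(sc$mean_jaccard, mean(rep(ceiling(0.6 * 49) / 49, 6)),
               tolerance = 1e-9)
})

test_that("F1 identity, threshold monotonicity and swap symmetry hold", {
  for (seed in 1:20) {
    maps <- random_toy_maps(seed + 100)
    ths <- seq(0.5, 0.9, by = 0.05)
    sc <- detection_scores(maps$target, maps$prediction, ths)
    per <- sc$per_threshold
    # Eq 4 (harmonic mean) == Eq 5 (2TP form)
    hm <- ifelse(per$precision + per$recall > 0,
                 2 * per$precision * per$recall / (per$precision + per$recall),
                 0)
    expect_equal(per$f1, hm, tolerance = 1e-12)
    expect_true(all(diff(per$precision) <= 1e-12))
    expect_true(all(diff(per$recall) <= 1e-12))
    expect_true(all(diff(per$f1) <= 1e-12))
    # swapping target/prediction swaps FP and FN
    m <- match_instances(maps$target, maps$prediction, 0.5)
    ms <- match_instances(maps$prediction, maps$target, 0.5)
    expect_equal(m$TP, ms$TP)
    expect_equal(m$FP, ms$FN)
    expect_equal(m$FN, ms$FP)
  }
})

test_that("Lin's CCC matches hand-computed oracles and bounds", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(lin_ccc(x, x)$ccc, 1)
  xc <- x - mean(x)
  expect_equal(lin_ccc(xc, -xc)$ccc, -1)
  # shifted line: moments by hand -> ccc = 2*2 / (2 + 2 + 0.01)
  y <- x + 0.1
  expect_equal(lin_ccc(x, y)$ccc, 4 / 4.01, tolerance = 1e-12)
  ci <- lin_ccc(x, y)$ci95
  expect_true(ci[1] <= 4 / 4.01 + 1e-9 && 4 / 4.01 <= ci[2] + 1e-9)
  expect_error(lin_ccc(x, c(1, 2)), "mismatch")
  expect_error(lin_ccc(x, rep(1, 5)), "variance")
  # |CCC| <= |Pearson r|
  set.seed(4)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10) + 0.5 * a
    expect_lte(abs(lin_ccc(a, b)$ccc), abs(cor(a, b)) + 1e-12)
  }
})

test_that("Bland-Altman bias and limits of agreement are exact", {
  x <- c(1, 2, 3, 4, 5)
  ba <- bland_altman(x, x)
  expect_equal(ba$bias, 0); expect_equal(ba$loa, c(0, 0))
  ba2 <- bland_altman(x, x + 0.5)
  expect_equal(ba2$bias, 0.5); expect_equal(ba2$loa, c(0.5, 0.5))
  # d = (-1, 1): sd = sqrt(2), loa = 0 +/- 1.96 sqrt(2)
  ba3 <- bland_altman(c(2, 2), c(1, 3))
  expect_equal(ba3$bias, 0, tolerance = 1e-12)
  expect_equal(ba3$loa, c(-1.96, 1.96) * sqrt(2), tolerance = 1e-12)
})

test_that("fibre pairing excludes borders and reports pooled rates", {
  n <- 40
  mk_h <- function(centres, radii) {
    fl <- matrix(0L, n, n)
    inns <- list()
    for (i in seq_along(radii)) {
      fl[disc_pixels(n, centres[i, 1], centres[i, 2], radii[i])] <- i
      inns[[i]] <- disc_pixels(n, centres[i, 1], centres[i, 2],
                               radii[i] - 3)
    }
    build_hierarchy(make_candidates(inns, c(n, n)),
                    instance_map(fl, "fibre"), NULL)
  }
  centres <- rbind(c(10, 10), c(30, 10), c(20, 30), c(39, 33))
  # last fibre touches the border on both sides
  th <- mk_h(centres, c(7, 6, 5, 6))
  expect_true(th$border_flag[4])
  pr <- mk_h(centres, c(7, 6, 5, 6))
  out <- pair_fibres_for_agreement(th, pr)
  expect_equal(nrow(out$paired), 3)               # border fibre excluded
  expect_equal(out$fn_rate, 0); expect_equal(out$fp_rate, 0)
  st <- agreement_stats(out, "area_fibre_um2")
  expect_equal(st$ccc, 1)
  expect_equal(st$bias, 0)

  # drop one prediction, add one spurious: fn 1/3, fp computed vs 3 preds
  pr2 <- mk_h(rbind(centres[1:2, ], c(33, 25)), c(7, 7, 5))
  out2 <- pair_fibres_for_agreement(th, pr2)
  expect_equal(out2$fn_rate, 1 / 3)
  expect_equal(out2$fp_rate, 1 / 3)
})
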