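#' Intersection over union of two pixel sets
#'
#' @param a,b Integer vectors of linear pixel indices on the same raster.
#' @return `|a & b| / |a | b|`.  Both sets empty is an error.
#' @export
iou <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) stop("IoU undefined for two empty regions", call. = FALSE)
  length(intersect(a, b)) / u
}

# pairwise overlap table between two label matrices:
# tibble(target, prediction, inter, area_t, area_p, iou)
overlap_table <- function(tlab, plab) {
  if (!identical(dim(tlab), dim(plab))) {
    stop("instance maps have mismatched dimensions", call. = FALSE)
  }
  area_t <- tabulate(tlab[tlab > 0L])
  area_p <- tabulate(plab[plab > 0L])
  both <- tlab > 0L & plab > 0L
  if (!any(both)) {
    return(tibble::tibble(target = integer(), prediction = integer(),
                          inter = integer(), iou = numeric()))
  }
  key <- paste(tlab[both], plab[both])
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " ", fixed = TRUE))
  t_id <- as.integer(parts[, 1]); p_id <- as.integer(parts[, 2])
  inter <- as.integer(tab)
  tibble::tibble(
    target = t_id, prediction = p_id, inter = inter,
    iou = inter / (area_t[t_id] + area_p[p_id] - inter))
}

#' Match instances one-to-one at an IoU threshold
#'
#' Candidate pairs with IoU at or above the threshold are accepted
#' greedily in order of decreasing IoU (ties broken by lower target, then
#' lower prediction label), enforcing a one-to-one pairing.  Thresholds
#' below 0.5 are rejected: below that value one target could legitimately
#' pair with two predictions (or vice versa) and the pairing would no
#' longer be well defined.
#'
#' @param target,prediction [instance_map()]s on the same raster.
#' @param threshold IoU threshold in `[0.5, 1]`.
#' @return An object of class `match_result` with the accepted `pairs`
#'   tibble and `TP`, `FP`, `FN` counts.
#' @export
match_instances <- function(target, prediction, threshold = 0.5) {
  stopifnot(inherits(target, "instance_map"),
            inherits(prediction, "instance_map"))
  if (threshold < 0.5 || threshold > 1) {
    stop("IoU threshold must lie in [0.5, 1]", call. = FALSE)
  }
  ov <- overlap_table(target$labels, prediction$labels)
  cand <- ov[ov$iou >= threshold, ]
  cand <- cand[order(-cand$iou, cand$target, cand$prediction), ]
  used_t <- integer(); used_p <- integer(); keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$target[i] %in% used_t) && !(cand$prediction[i] %in% used_p)) {
      keep[i] <- TRUE
      used_t <- c(used_t, cand$target[i])
      used_p <- c(used_p, cand$prediction[i])
    }
  }
  pairs <- cand[keep, c("target", "prediction", "iou")]
  n_t <- length(setdiff(unique(as.vector(target$labels)), 0L))
  n_p <- length(setdiff(unique(as.vector(prediction$labels)), 0L))
  structure(
    list(threshold = threshold, pairs = pairs,
         TP = nrow(pairs), FP = n_p - nrow(pairs), FN = n_t - nrow(pairs),
         n_target = n_t, n_prediction = n_p),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> IoU >= %.2f: TP %d, FP %d, FN %d\n",
              x$threshold, x$TP, x$FP, x$FN))
  invisible(x)
}

#' Detection scores over a range of IoU thresholds
#'
#' Per threshold: precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and
#' `F1 = 2 TP / (2 TP + FN + FP)` (the harmonic mean of precision and
#' recall).  Averages are arithmetic means over the threshold list, and
#' the mean Jaccard index is the mean over *target* objects of each
#' object's best IoU against any prediction.
#'
#' @param targets,predictions [instance_map()]s on the same raster.
#' @param thresholds IoU thresholds (default 0.5 to 0.9, step 0.05).
#' @return An object of class `detection_scores`.
#' @export
detection_scores <- function(targets, predictions,
                             thresholds = seq(0.5, 0.9, by = 0.05)) {
  if (!length(thresholds)) stop("empty threshold list", call. = FALSE)
  n_t <- length(setdiff(unique(as.vector(targets$labels)), 0L))
  if (n_t == 0L) stop("no target objects", call. = FALSE)
  per <- purrr::map_dfr(thresholds, function(th) {
    m <- match_instances(targets, predictions, th)
    tibble::tibble(
      threshold = th, TP = m$TP, FP = m$FP, FN = m$FN,
      precision = if (m$TP + m$FP > 0) m$TP / (m$TP + m$FP) else 0,
      recall = m$TP / (m$TP + m$FN),
      f1 = if (2 * m$TP + m$FN + m$FP > 0) {
        2 * m$TP / (2 * m$TP + m$FN + m$FP)
      } else 0)
  })
  ov <- overlap_table(targets$labels, predictions$labels)
  best <- rep(0, n_t)
  if (nrow(ov)) {
    agg <- tapply(ov$iou, ov$target, max)
    best[as.integer(names(agg))] <- agg
  }
  structure(
    list(per_threshold = per,
         avg_precision = mean(per$precision), avg_recall = mean(per$recall),
         avg_f1 = mean(per$f1), mean_jaccard = mean(best)),
    class = "detection_scores")
}

#' @export
print.detection_scores <- function(x, ...) {
  cat(sprintf(
    "<detection_scores> avg F1 %.3f, precision %.3f, recall %.3f, mean Jaccard %.3f (%d thresholds)\n",
    x$avg_f1, x$avg_precision, x$avg_recall, x$mean_jaccard,
    nrow(x$per_threshold)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.detection_scores <- function(x, ...) x$per_threshold

#' @exportS3Method generics::glance
glance.detection_scores <- function(x, ...) {
  tibble::tibble(avg_precision = x$avg_precision, avg_recall = x$avg_recall,
                 avg_f1 = x$avg_f1, mean_jaccard = x$mean_jaccard)
}

#' Pair fibres between two hierarchies for agreement analysis
#'
#' Border-touching fibres are removed from *both* sides first (incomplete
#' fibres have no reliable morphometry), the remaining fibres are matched
#' one-to-one at `min_iou`, and the paired per-fibre measurements are
#' returned together with pooled false-negative / false-positive rates
#' (unmatched fraction of targets / predictions, border fibres excluded
#' from the denominators).
#'
#' @param target_h,pred_h [build_hierarchy()] results for the same image.
#' @param min_iou Minimum fibre IoU for a pair (default 0.5).
#' @param exclude_border Drop border-touching fibres first (default TRUE).
#' @return A list with `paired` (tibble of `_target` / `_pred` measurement
#'   columns), `fn_rate` and `fp_rate`.
#' @export
pair_fibres_for_agreement <- function(target_h, pred_h, min_iou = 0.5,
                                      exclude_border = TRUE) {
  stopifnot(inherits(target_h, "fibre_hierarchy"),
            inherits(pred_h, "fibre_hierarchy"))
  if (!nrow(target_h)) stop("empty target hierarchy", call. = FALSE)
  if (exclude_border) {
    target_h <- target_h[!target_h$border_flag, ]
    pred_h <- pred_h[!pred_h$border_flag, ]
  }
  mt <- measure_fibres(target_h)
  mp <- measure_fibres(pred_h)
  t_map <- hierarchy_maps(target_h)$fibre
  p_map <- hierarchy_maps(pred_h)$fibre
  m <- match_instances(t_map, p_map, min_iou)
  join_pair <- function(t, p) {
    cbind(
      dplyr::rename_with(mt[mt$fibre_id == t, ], ~ paste0(.x, "_target")),
      dplyr::rename_with(mp[mp$fibre_id == p, ], ~ paste0(.x, "_pred")))
  }
  rows <- if (nrow(m$pairs)) {
    purrr::map2_dfr(m$pairs$target, m$pairs$prediction, join_pair)
  } else {
    cbind(dplyr::rename_with(mt[0, ], ~ paste0(.x, "_target")),
          dplyr::rename_with(mp[0, ], ~ paste0(.x, "_pred")))
  }
  list(
    paired = tibble::as_tibble(rows),
    fn_rate = if (nrow(mt)) (nrow(mt) - m$TP) / nrow(mt) else 0,
    fp_rate = if (nrow(mp)) (nrow(mp) - m$TP) / nrow(mp) else 0)
}

#' Lin's concordance correlation coefficient
#'
#' `ccc = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' 1/n moment estimators.  Perfect concordance (ccc = 1) requires the
#' points to fall on the identity line, so the statistic penalises both
#' decorrelation and systematic offset.  The 95% CI uses the Fisher
#' z-transform with Lin's asymptotic standard error.
#'
#' @param x,y Equal-length numeric vectors (n >= 3), non-zero variance.
#' @return List with `ccc` and `ci95 = c(low, high)`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired values", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  if (sx2 == 0 || sy2 == 0) stop("zero variance", call. = FALSE)
  sxy <- mean((x - mx) * (y - my))
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / (sx2 * sy2)^0.25
  if (abs(ccc) >= 1 || abs(r) >= 1) {
    ci <- c(ccc, ccc)
  } else {
    se_z <- sqrt(
      ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
         2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
         ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2))
    z <- atanh(ccc)
    ci <- tanh(z + c(-1, 1) * 1.96 * se_z)
  }
  list(ccc = ccc, ci95 = ci)
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences are prediction minus target; bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 * SD` (sample SD, n - 1).
#'
#' @param x Target measurements.
#' @param y Prediction measurements (same length).
#' @return List with `bias`, `loa = c(low, high)` and `sd_diff`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 paired values", call. = FALSE)
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa = bias + c(-1.96, 1.96) * s, sd_diff = s)
}

#' Agreement statistics for one paired measurement
#'
#' Convenience wrapper combining [lin_ccc()] and [bland_altman()] on one
#' measurement column of a [pair_fibres_for_agreement()] result.
#'
#' @param pairing A [pair_fibres_for_agreement()] result.
#' @param measure Measurement name, e.g. `"area_fibre_um2"`, `"g_myelin"`,
#'   `"g_axon"`.
#' @return An object of class `agreement_stats`.
#' @export
agreement_stats <- function(pairing, measure = "area_fibre_um2") {
  x <- pairing$paired[[paste0(measure, "_target")]]
  y <- pairing$paired[[paste0(measure, "_pred")]]
  cc <- lin_ccc(x, y)
  ba <- bland_altman(x, y)
  structure(
    list(measure = measure, ccc = cc$ccc, ccc_ci95 = cc$ci95,
         bias = ba$bias, loa = ba$loa, n_pairs = length(x),
         fn_rate = pairing$fn_rate, fp_rate = pairing$fp_rate,
         x = x, y = y),
    class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf(
    "<agreement_stats:%s> CCC %.4f (95%% CI %.4f-%.4f), bias %.4g, LoA [%.4g, %.4g], n %d\n",
    x$measure, x$ccc, x$ccc_ci95[1], x$ccc_ci95[2], x$bias,
    x$loa[1], x$loa[2], x$n_pairs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.agreement_stats <- function(x, ...) {
  tibble::tibble(measure = x$measure, ccc = x$ccc,
                 ccc_low = x$ccc_ci95[1], ccc_high = x$ccc_ci95[2],
                 bias = x$bias, loa_low = x$loa[1], loa_high = x$loa[2],
                 n_pairs = x$n_pairs, fn_rate = x$fn_rate,
                 fp_rate = x$fp_rate)
}

#' @exportS3Method generics::glance
glance.agreement_stats <- function(x, ...) tidy.agreement_stats(x)
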