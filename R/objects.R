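OBJECT_CLASSES <- c("axon_large", "axon_small", "inner_tongue")

#' Extract axoplasm instance candidates from a probability stack
#'
#' The axoplasm probability channel is Gaussian-smoothed, binarised at
#' `>= threshold`, labelled into 8-connected components, and components
#' smaller than `min_size_px` are removed.  Labels are renumbered `1..n`
#' in raster-scan order of each component's first pixel.
#'
#' @param prob A [prob_stack()].
#' @param smooth_sigma Gaussian smoothing scale in pixels (default 2.0).
#' @param threshold Probability threshold (default 0.6).
#' @param min_size_px Minimum component size in pixels (default 10).
#' @return An [instance_map()] of kind `"axon"` (candidate axoplasm
#'   instances; may be empty).
#' @export
axoplasm_candidates <- function(prob, smooth_sigma = 2.0, threshold = 0.6,
                                min_size_px = 10L) {
  stopifnot(inherits(prob, "prob_stack"))
  ax <- prob$p[, , "axoplasm"]
  if (smooth_sigma > 0) ax <- filter_gaussian(ax, smooth_sigma, 0, 0)
  lab <- label_components(ax >= threshold, 8)
  if (max(lab) > 0L && min_size_px > 1L) {
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < min_size_px)
    if (length(drop)) lab[lab %in% drop] <- 0L
    lab <- renumber_raster_order(lab)
  }
  instance_map(lab, "axon", prob$pixel_size_um)
}

# shoelace area of a closed polygon given vertex matrix [x, y]
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# convex hull area of a pixel set, using the 4 corner points of each cell
pixel_hull_area <- function(rc) {
  corners <- rbind(
    cbind(rc[, 1] - 0.5, rc[, 2] - 0.5), cbind(rc[, 1] - 0.5, rc[, 2] + 0.5),
    cbind(rc[, 1] + 0.5, rc[, 2] - 0.5), cbind(rc[, 1] + 0.5, rc[, 2] + 0.5)
  )
  h <- grDevices::chull(corners)
  polygon_area(corners[h, , drop = FALSE])
}

# eccentricity from normalised second central moments (0 = circle)
moment_eccentricity <- function(rc) {
  if (nrow(rc) < 2L) return(0)
  mu <- colMeans(rc)
  dr <- rc[, 1] - mu[1]; dc <- rc[, 2] - mu[2]
  m20 <- mean(dr^2); m02 <- mean(dc^2); m11 <- mean(dr * dc)
  half <- (m20 + m02) / 2
  disc <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  lmax <- half + disc; lmin <- half - disc
  if (lmax <= 0) return(0)
  sqrt(max(0, 1 - lmin / lmax))
}

# 4-connected exposed-edge count (perimeter in pixel-edge units)
region_perimeter <- function(idx, dims) {
  m <- matrix(FALSE, dims[1] + 2L, dims[2] + 2L)
  rc <- idx_to_rc(idx, dims[1])
  m[cbind(rc[, 1] + 1L, rc[, 2] + 1L)] <- TRUE
  inner <- m[2:(dims[1] + 1L), 2:(dims[2] + 1L), drop = FALSE]
  nb <- m[1:dims[1], 2:(dims[2] + 1L)] + m[3:(dims[1] + 2L), 2:(dims[2] + 1L)] +
    m[2:(dims[1] + 1L), 1:dims[2]] + m[2:(dims[1] + 1L), 3:(dims[2] + 2L)]
  sum((4L - nb)[inner])
}

#' Shape and intensity features for candidate objects
#'
#' One row per labelled object: shape descriptors (area, perimeter,
#' circularity, convex area, solidity, eccentricity, circle-equivalent
#' diameter, bounding-box extent) and intensity-distribution statistics of
#' the raw image within the object (mean, SD, min, max, five quantiles and
#' a fixed 10-bin histogram over `[0, 1]`).  Location features (centroids,
#' bounding-box positions) are deliberately excluded so the classifier is
#' position-invariant.
#'
#' @param candidates An [instance_map()] of candidates.
#' @param img The [image2d()] the candidates were derived from.
#' @return A tibble with a `label` column and one numeric column per
#'   feature.
#' @export
object_feature_table <- function(candidates, img) {
  stopifnot(inherits(candidates, "instance_map"), inherits(img, "image2d"))
  dims <- dim(candidates$labels)
  stopifnot(identical(dims, dim(img$pixels)))
  px_sets <- split_label_pixels(candidates$labels)
  if (!length(px_sets)) {
    return(tibble::tibble(label = integer()))
  }
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  rows <- purrr::imap(px_sets, function(idx, lab) {
    rc <- idx_to_rc(idx, dims[1])
    area <- length(idx)
    per <- region_perimeter(idx, dims)
    hull <- pixel_hull_area(rc)
    bbox <- (diff(range(rc[, 1])) + 1L) * (diff(range(rc[, 2])) + 1L)
    v <- img$pixels[idx]
    qv <- quantile(v, qs, names = FALSE)
    hist_counts <- tabulate(pmin(floor(v * 10) + 1L, 10L), nbins = 10L) / area
    c(label = as.integer(lab),
      area = area, perimeter = per,
      circularity = if (per > 0) 4 * pi * area / per^2 else 0,
      convex_area = hull,
      solidity = if (hull > 0) area / hull else 1,
      eccentricity = moment_eccentricity(rc),
      equiv_diameter = 2 * sqrt(area / pi),
      extent = area / bbox,
      int_mean = mean(v), int_sd = if (area > 1) sd(v) else 0,
      int_min = min(v), int_max = max(v),
      setNames(qv, sprintf("int_q%02d", round(qs * 100))),
      setNames(hist_counts, sprintf("int_hist%02d", 1:10)))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$label <- as.integer(out$label)
  dplyr::arrange(out, .data$label)
}

#' Train the object classifier
#'
#' A random forest over the three annotated object classes (`axon_large`,
#' `axon_small`, `inner_tongue`).  Object kinds that were not annotated at
#' training time are simply absent from the label set; downstream their
#' predictions are discarded by the Stage-3 overlap gate.
#'
#' @param features Feature tibble from [object_feature_table()].
#' @param labels Character/factor vector of true classes, parallel to the
#'   rows of `features`.
#' @param seed Integer seed.
#' @param num_trees Trees in the forest (default 100).
#' @return An object of class `object_model`.
#' @export
train_object_classifier <- function(features, labels, seed = 1L,
                                    num_trees = 100L) {
  stopifnot(nrow(features) == length(labels))
  labels <- factor(as.character(labels), levels = OBJECT_CLASSES)
  if (anyNA(labels)) {
    stop("labels must be one of: ", paste(OBJECT_CLASSES, collapse = ", "),
         call. = FALSE)
  }
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric, TRUE)],
                       c("label"))
  dat <- as.data.frame(features[, feat_cols])
  dat$.class <- droplevels(labels)
  forest <- ranger::ranger(
    dependent.variable.name = ".class", data = dat,
    num.trees = num_trees, seed = seed, num.threads = 1
  )
  structure(
    list(forest = forest, feature_names = feat_cols,
         classes = levels(dat$.class), rng_seed = as.integer(seed),
         format_version = "myelinseg-object-1"),
    class = "object_model"
  )
}

#' @export
print.object_model <- function(x, ...) {
  cat(sprintf("<object_model> %d classes, %d features, OOB err %.4f\n",
              length(x$classes), length(x$feature_names),
              x$forest$prediction.error))
  invisible(x)
}

#' Classify candidate objects
#'
#' Assigns each candidate one of the trained object classes.  With
#' `model = NULL` a model-free geometric rule is applied instead:
#' low-solidity objects (crescent-shaped, solidity < 0.8) are called
#' `inner_tongue`, the rest are axons, split into large/small at the
#' median circle-equivalent diameter.
#'
#' @param model An [train_object_classifier()] model, or `NULL`.
#' @param features Feature tibble from [object_feature_table()].
#' @return The feature tibble with a `predicted_class` column added.
#' @export
classify_objects <- function(model, features) {
  if (nrow(features) == 0L) {
    features$predicted_class <- character()
    return(features)
  }
  if (is.null(model)) {
    tongue <- features$solidity < 0.8
    big <- features$equiv_diameter >= stats::median(features$equiv_diameter)
    cls <- ifelse(tongue, "inner_tongue",
                  ifelse(big, "axon_large", "axon_small"))
  } else {
    stopifnot(inherits(model, "object_model"))
    missing <- setdiff(model$feature_names, names(features))
    if (length(missing)) {
      stop("feature schema mismatch; missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    dat <- as.data.frame(features[, model$feature_names])
    cls <- as.character(
      predict(model$forest, data = dat, num.threads = 1)$predictions
    )
  }
  features$predicted_class <- cls
  features
}
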