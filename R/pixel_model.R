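#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats quantile sd var cor predict setNames
#' @importFrom utils head modifyList
NULL

PIXEL_CLASSES_A <- c("compact_myelin", "axoplasm", "membrane", "mitochondria")
PIXEL_CLASSES_B <- c("compact_myelin", "axoplasm", "membrane")

# autocontext channels: stage-A class probabilities plus their Gaussian
# smoothings at every feature scale
autocontext_channels <- function(prob_arr, class_names, scales) {
  d <- dim(prob_arr)
  out <- list()
  for (k in seq_len(d[3])) {
    pk <- prob_arr[, , k]
    out[[sprintf("ac_%s", class_names[k])]] <- pk
    for (s in scales) {
      if (s > min(d[1:2]) / 2) next
      out[[sprintf("ac_%s_s%g", class_names[k], s)]] <-
        filter_gaussian(pk, s, 0, 0)
    }
  }
  m <- vapply(out, as.vector, numeric(d[1] * d[2]))
  colnames(m) <- names(out)
  m
}

ranger_prob_predict <- function(forest, feats, classes) {
  pr <- predict(forest, data = as.data.frame(feats), num.threads = 1)$predictions
  missing <- setdiff(classes, colnames(pr))
  for (m in missing) pr <- cbind(pr, setNames(data.frame(0), m))
  as.matrix(pr[, classes, drop = FALSE])
}

#' Train the autocontext pixel classifier
#'
#' Two sequential random-forest pixel classifications: stage A is trained
#' on the raw multi-scale features with up to four classes (compact
#' myelin, axoplasm, membrane, mitochondria); stage B is trained on the
#' raw features plus stage A's probability channels (and their Gaussian
#' smoothings at the feature scales), with mitochondria scribbles merged
#' into the axoplasm class so that the final prediction cannot leave
#' mitochondria-shaped holes in axons.
#'
#' @param images List of [image2d()] (normalised).
#' @param scribbles List of integer matrices aligned to `images`: 0 =
#'   unlabelled, 1 = compact myelin, 2 = axoplasm, 3 = membrane,
#'   4 = mitochondria (optional class).
#' @param cfg A [feature_config()].
#' @param seed Integer seed controlling forest training.
#' @param num_trees Trees per forest (default 100).
#' @return An object of class `pixel_model`.
#' @export
train_pixel_autocontext <- function(images, scribbles, cfg = feature_config(),
                                    seed = 1L, num_trees = 100L) {
  if (inherits(images, "image2d")) images <- list(images)
  if (is.matrix(scribbles)) scribbles <- list(scribbles)
  stopifnot(length(images) == length(scribbles))
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]$pixels), dim(scribbles[[i]]))) {
      stop("scribble raster ", i, " is not aligned to its image", call. = FALSE)
    }
  }
  all_codes <- sort(unique(unlist(lapply(scribbles, function(s) s[s > 0L]))))
  required <- 1:3
  if (!all(required %in% all_codes)) {
    miss <- PIXEL_CLASSES_A[setdiff(required, all_codes)]
    stop("no scribbles for class(es): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  classes_a <- PIXEL_CLASSES_A[all_codes]

  feats <- lapply(images, pixel_feature_stack, cfg = cfg)
  rows_a <- list(); y_a <- list()
  for (i in seq_along(images)) {
    idx <- which(scribbles[[i]] > 0L)
    rows_a[[i]] <- feats[[i]][idx, , drop = FALSE]
    y_a[[i]] <- PIXEL_CLASSES_A[scribbles[[i]][idx]]
  }
  train_a <- as.data.frame(do.call(rbind, rows_a))
  train_a$.class <- factor(unlist(y_a), levels = classes_a)
  forest_a <- ranger::ranger(
    dependent.variable.name = ".class", data = train_a,
    probability = TRUE, num.trees = num_trees, seed = seed, num.threads = 1
  )

  # stage B: same pixels, mitochondria relabelled to axoplasm, features
  # augmented with stage-A full-image probability channels
  rows_b <- list(); y_b <- list()
  for (i in seq_along(images)) {
    d <- dim(images[[i]]$pixels)
    pr <- ranger_prob_predict(forest_a, feats[[i]], classes_a)
    pr_arr <- array(pr, c(d[1], d[2], length(classes_a)))
    ac <- autocontext_channels(pr_arr, classes_a, cfg$scales_sigma)
    idx <- which(scribbles[[i]] > 0L)
    rows_b[[i]] <- cbind(feats[[i]][idx, , drop = FALSE], ac[idx, , drop = FALSE])
    lb <- scribbles[[i]][idx]
    lb[lb == 4L] <- 2L
    y_b[[i]] <- PIXEL_CLASSES_B[lb]
  }
  train_b <- as.data.frame(do.call(rbind, rows_b))
  train_b$.class <- factor(unlist(y_b), levels = PIXEL_CLASSES_B)
  forest_b <- ranger::ranger(
    dependent.variable.name = ".class", data = train_b,
    probability = TRUE, num.trees = num_trees, seed = seed + 1L, num.threads = 1
  )

  structure(
    list(stage_a = forest_a, stage_b = forest_b,
         classes_a = classes_a, classes_b = PIXEL_CLASSES_B,
         feature_config = cfg, rng_seed = as.integer(seed),
         oob_error_a = forest_a$prediction.error,
         oob_error_b = forest_b$prediction.error,
         format_version = "myelinseg-pixel-1"),
    class = "pixel_model"
  )
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf(
    "<pixel_model> autocontext forest: stage A %d classes (OOB err %.4f), stage B %d classes (OOB err %.4f)\n",
    length(x$classes_a), x$oob_error_a, length(x$classes_b), x$oob_error_b))
  invisible(x)
}

#' Predict class probabilities for an image
#'
#' Runs both autocontext passes and returns the final three-channel
#' probability stack (myelin, axoplasm, membrane); channels sum to one at
#' every pixel.
#'
#' @param model A [train_pixel_autocontext()] model.
#' @param img An [image2d()] normalised like the training data.
#' @return A [prob_stack()].
#' @export
predict_probabilities <- function(model, img) {
  stopifnot(inherits(model, "pixel_model"), inherits(img, "image2d"))
  d <- dim(img$pixels)
  feats <- pixel_feature_stack(img, model$feature_config)
  pr_a <- ranger_prob_predict(model$stage_a, feats, model$classes_a)
  pr_arr <- array(pr_a, c(d[1], d[2], length(model$classes_a)))
  ac <- autocontext_channels(pr_arr, model$classes_a,
                             model$feature_config$scales_sigma)
  pr_b <- ranger_prob_predict(model$stage_b, cbind(feats, ac), model$classes_b)
  p <- array(pr_b, c(d[1], d[2], 3))
  prob_stack(p, img$pixel_size_um, renormalise = TRUE)
}

#' Save / load a trained model bundle
#'
#' Persists the pixel and/or object models plus their configuration as a
#' single serialized bundle with a format-version string.
#'
#' @param pixel_model,object_model Trained models (either may be `NULL`).
#' @param path Destination file.
#' @return `save_models()` returns `path` invisibly; `load_models()`
#'   returns the bundle list.
#' @export
save_models <- function(pixel_model = NULL, object_model = NULL, path) {
  bundle <- list(format_version = "myelinseg-bundle-1",
                 pixel_model = pixel_model, object_model = object_model)
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_models
#' @export
load_models <- function(path) {
  bundle <- readRDS(path)
  if (!identical(bundle$format_version, "myelinseg-bundle-1")) {
    stop("unrecognised model bundle format", call. = FALSE)
  }
  bundle
}
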