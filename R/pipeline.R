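#' Default segmentation parameters
#'
#' All stage parameters in one list.  Values stated by the standard
#' workflow are the defaults: candidate smoothing sigma 2.0, probability
#' threshold 0.6, minimum candidate size 10 px; Stage-1 gates (area
#' window, axoplasm-probability gate) and the Stage-3 overlap fraction
#' are exposed here as well.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of parameters.
#' @export
seg_params <- function(...) {
  defaults <- list(
    min_area_px = 50L, max_area_fraction = 0.05, axoplasm_gate = 0.4,
    close_radius = 1L,
    smooth_sigma = 2.0, threshold = 0.6, min_size_px = 10L,
    overlap_fraction = 0.5,
    correction = "dilate", correction_radius = 2L,
    duplicate_inner_as_axon = TRUE)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  modifyList(defaults, overrides)
}

#' Run the full three-stage segmentation on one image
#'
#' Executes inner-region detection (Stage 1), seeded fibre expansion
#' (Stage 2) and axon selection (Stage 3), applies optional batch
#' curation between stages, corrects selected axons, builds the fibre
#' hierarchy and measures per-fibre morphometry.
#'
#' @param prob A [prob_stack()] for the image.
#' @param img The corresponding [image2d()]; needed for object features.
#' @param object_model An [train_object_classifier()] model, or `NULL`
#'   for the model-free geometric rule.
#' @param params A [seg_params()] list.
#' @param curation Optional curation override (list from
#'   [read_curation()]) with elements `stage1` and/or `stage3`.
#' @return An object of class `segmentation`: stage outputs, the
#'   [build_hierarchy()] result, the morphometry tibble and the semantic
#'   mask.
#' @export
segment_image <- function(prob, img, object_model = NULL,
                          params = seg_params(), curation = NULL) {
  stopifnot(inherits(prob, "prob_stack"), inherits(img, "image2d"))
  t0 <- proc.time()[["elapsed"]]
  s1 <- stage1_inner_regions(
    prob, min_area_px = params$min_area_px,
    max_area_fraction = params$max_area_fraction,
    axoplasm_gate = params$axoplasm_gate,
    close_radius = params$close_radius)
  if (!is.null(curation$stage1)) s1 <- apply_curation(s1, curation$stage1)
  t1 <- proc.time()[["elapsed"]]

  fibres <- stage2_fibres(s1)
  inner_map <- candidates_to_map(s1, "inner_region")
  t2 <- proc.time()[["elapsed"]]

  cand <- axoplasm_candidates(
    prob, smooth_sigma = params$smooth_sigma,
    threshold = params$threshold, min_size_px = params$min_size_px)
  feats <- object_feature_table(cand, img)
  cls <- classify_objects(object_model, feats)
  axons <- stage3_axons(cls, cand, inner_map,
                        overlap_fraction = params$overlap_fraction)
  if (!is.null(curation$stage3)) axons <- apply_curation(axons, curation$stage3)
  if (params$correction != "none" && nrow(axons)) {
    dims <- dim(inner_map$labels)
    sel <- which(axons$state == "selected")
    axons$pixels[sel] <- lapply(
      axons$pixels[sel], correct_axon, dims = dims,
      method = params$correction, radius = params$correction_radius)
  }
  t3 <- proc.time()[["elapsed"]]

  hier <- build_hierarchy(
    s1, fibres, axons,
    duplicate_inner_as_axon = params$duplicate_inner_as_axon)
  morpho <- measure_fibres(hier)
  semantic <- semantic_from_hierarchy(hier)
  t4 <- proc.time()[["elapsed"]]

  structure(
    list(stage1 = s1, fibres = fibres, axon_candidates = axons,
         hierarchy = hier, morphometry = morpho, semantic = semantic,
         params = params,
         timings = c(stage1 = t1 - t0, stage2 = t2 - t1, stage3 = t3 - t2,
                     postprocess = t4 - t3)),
    class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation> %d fibres, %d selected axons; timings (s): %s\n",
    nrow(x$hierarchy), sum(x$axon_candidates$state == "selected"),
    paste(sprintf("%s %.2f", names(x$timings), x$timings), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.segmentation <- function(x, ...) x$morphometry

#' @exportS3Method generics::glance
glance.segmentation <- function(x, ...) {
  tibble::tibble(
    n_fibres = nrow(x$hierarchy),
    n_axons_selected = sum(x$axon_candidates$state == "selected"),
    n_axons_duplicated = sum(x$hierarchy$axon_duplicated),
    mean_g_myelin = mean(x$morphometry$g_myelin),
    mean_g_axon = mean(x$morphometry$g_axon))
}
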