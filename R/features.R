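#' Multi-scale pixel feature configuration
#'
#' The feature bank computed per Gaussian scale sigma (in pixels):
#'
#' * **intensity** — Gaussian smoothing;
#' * **edge** — Laplacian of Gaussian, Gaussian gradient magnitude, and
#'   difference of Gaussians (sigma vs 0.66 sigma);
#' * **texture** — the two eigenvalues of the Gaussian-smoothed structure
#'   tensor and the two eigenvalues of the Hessian.
#'
#' The smallest scale contributes smoothing only.  The default scale list
#' is (0.3, 0.7, 1.0, 1.6, 3.5, 5.0, 10.0, 15.0, 30.0, 50.0).
#'
#' @param scales_sigma Strictly increasing positive Gaussian scales (px).
#' @param feature_families Subset of `c("intensity", "edge", "texture")`.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(scales_sigma = c(0.3, 0.7, 1.0, 1.6, 3.5, 5.0,
                                            10.0, 15.0, 30.0, 50.0),
                           feature_families = c("intensity", "edge", "texture")) {
  if (any(scales_sigma <= 0) || any(diff(scales_sigma) <= 0)) {
    stop("`scales_sigma` must be strictly increasing and positive",
         call. = FALSE)
  }
  feature_families <- match.arg(feature_families,
                                c("intensity", "edge", "texture"),
                                several.ok = TRUE)
  structure(
    list(scales_sigma = scales_sigma, feature_families = feature_families),
    class = "feature_config"
  )
}

# eigenvalues of a field of symmetric 2x2 matrices [[a, b], [b, c]];
# returns list(hi, lo), hi >= lo elementwise
sym2x2_eigen <- function(a, b, c) {
  tr2 <- (a + c) / 2
  disc <- sqrt(pmax(((a - c) / 2)^2 + b^2, 0))
  list(hi = tr2 + disc, lo = tr2 - disc)
}

#' Multi-scale per-pixel feature stack
#'
#' Computes the feature bank of [feature_config()] for one image.  Channel
#' order is deterministic: scales in increasing order and, within a scale,
#' `gauss`, `log`, `ggm`, `dog`, `st_hi`, `st_lo`, `hess_hi`, `hess_lo`
#' (restricted to the requested families; the smallest scale contributes
#' only `gauss`).  Scales exceeding half the shorter image side are
#' skipped with a warning.
#'
#' @param img An [image2d()] (normalised intensities).
#' @param cfg A [feature_config()].
#' @return Numeric matrix with one row per pixel (column-major pixel
#'   order) and one named column per feature channel.
#' @export
pixel_feature_stack <- function(img, cfg = feature_config()) {
  stopifnot(inherits(img, "image2d"), inherits(cfg, "feature_config"))
  x <- img$pixels
  half_side <- min(dim(x)) / 2
  scales <- cfg$scales_sigma
  usable <- scales <= half_side
  if (any(!usable)) {
    warning(sprintf("skipping scales larger than half the image side: %s",
                    paste(scales[!usable], collapse = ", ")))
    scales <- scales[usable]
  }
  if (!length(scales)) stop("no usable scales for this image", call. = FALSE)
  fams <- cfg$feature_families
  chans <- list()
  smallest <- scales[1]
  for (s in scales) {
    tag <- function(nm) sprintf("%s_s%g", nm, s)
    sm <- filter_gaussian(x, s, 0, 0)
    if ("intensity" %in% fams) chans[[tag("gauss")]] <- sm
    if (s == smallest) next
    gr <- filter_gaussian(x, s, 1, 0)   # d/dy
    gc <- filter_gaussian(x, s, 0, 1)   # d/dx
    grr <- filter_gaussian(x, s, 2, 0)
    gcc <- filter_gaussian(x, s, 0, 2)
    grc <- filter_gaussian(x, s, 1, 1)
    if ("edge" %in% fams) {
      chans[[tag("log")]] <- grr + gcc
      chans[[tag("ggm")]] <- sqrt(gr^2 + gc^2)
      chans[[tag("dog")]] <- sm - filter_gaussian(x, 0.66 * s, 0, 0)
    }
    if ("texture" %in% fams) {
      rho <- max(0.5 * s, 0.3)   # integration scale of the structure tensor
      st <- sym2x2_eigen(
        filter_gaussian(gr^2, rho, 0, 0),
        filter_gaussian(gr * gc, rho, 0, 0),
        filter_gaussian(gc^2, rho, 0, 0)
      )
      chans[[tag("st_hi")]] <- st$hi
      chans[[tag("st_lo")]] <- st$lo
      he <- sym2x2_eigen(grr, grc, gcc)
      chans[[tag("hess_hi")]] <- he$hi
      chans[[tag("hess_lo")]] <- he$lo
    }
  }
  out <- vapply(chans, as.vector, numeric(length(x)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- names(chans)
  out
}
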