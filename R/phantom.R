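# Paint codes used internally by the generator (not the semantic codes):
# 0 extracellular, 1 axoplasm, 2 inner tongue, 3 membrane, 4 compact
# myelin, 5 mitochondrion.

#' Specification of a synthetic TEM phantom
#'
#' Defines the population an artificial corpus-callosum cross-section is
#' drawn from: dark compact-myelin rings around lighter axoplasm, a
#' crescent-shaped inner tongue between axon and innermost myelin, a 1-px
#' darker membrane line at the axon boundary, occasional mitochondria,
#' unmyelinated axons, and a wide spread of fibre sizes and g-ratios.
#'
#' Size and shape are sampled per fibre: the axon is an ellipse with
#' geometric-mean radius drawn from a lognormal (clamped to
#' `[radius min, max]`), axis ratio uniform in `[1, 2]`; the target myelin
#' g-ratio comes from a truncated normal; the inner tongue occupies a
#' Beta-distributed fraction of the inner-region area and is shaped as a
#' crescent by offsetting the axon inside the inner ellipse until they
#' touch.
#'
#' @param image_size_px Side of the square image (default 768).
#' @param pixel_size_um Pixel size (default 8.4182e-3, the working
#'   resolution of 4x-downsampled 7.1K-magnification TEM).
#' @param n_fibres Number of myelinated fibres to place (default 50).
#' @param axon_radius Lognormal parameters and clamp for the axon
#'   geometric-mean radius in px.
#' @param target_g_myelin Truncated-normal parameters for the myelin
#'   g-ratio.
#' @param tongue_fraction Beta parameters (and upper clamp) for the
#'   fraction of the inner region occupied by the tongue.
#' @param p_unmyelinated Expected unmyelinated axons per myelinated fibre.
#' @param p_mitochondria Probability a fibre's axon contains a
#'   mitochondrion.
#' @param intensity_levels Named intensities in `[0, 1]` for
#'   `extracellular`, `axoplasm`, `tongue`, `membrane`, `myelin`,
#'   `mitochondria`.
#' @param noise_sd Additive Gaussian noise SD.
#' @param blur_sigma_px Gaussian blur applied before noise.
#' @param seed Integer seed; the phantom is fully reproducible from it.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size_px = 768L,
                         pixel_size_um = 8.4182e-3,
                         n_fibres = 50L,
                         axon_radius = list(meanlog = log(14), sdlog = 0.25,
                                            min = 10, max = 40),
                         target_g_myelin = list(mean = 0.75, sd = 0.06,
                                                lo = 0.60, hi = 0.90),
                         tongue_fraction = list(a = 2, b = 8, max = 0.45),
                         p_unmyelinated = 0.15,
                         p_mitochondria = 0.3,
                         intensity_levels = c(extracellular = 0.80,
                                              axoplasm = 0.75, tongue = 0.65,
                                              membrane = 0.35, myelin = 0.15,
                                              mitochondria = 0.25),
                         noise_sd = 0.05,
                         blur_sigma_px = 0.7,
                         seed = 1L) {
  stopifnot(
    image_size_px >= 32L, pixel_size_um > 0, n_fibres >= 0L,
    target_g_myelin$lo > 0, target_g_myelin$hi < 1,
    target_g_myelin$lo < target_g_myelin$hi,
    tongue_fraction$max >= 0, tongue_fraction$max < 1,
    p_unmyelinated >= 0, p_unmyelinated <= 1,
    p_mitochondria >= 0, p_mitochondria <= 1,
    all(intensity_levels >= 0 & intensity_levels <= 1),
    noise_sd >= 0, blur_sigma_px >= 0)
  structure(
    list(image_size_px = as.integer(image_size_px),
         pixel_size_um = pixel_size_um, n_fibres = as.integer(n_fibres),
         axon_radius = axon_radius, target_g_myelin = target_g_myelin,
         tongue_fraction = tongue_fraction,
         p_unmyelinated = p_unmyelinated, p_mitochondria = p_mitochondria,
         intensity_levels = intensity_levels, noise_sd = noise_sd,
         blur_sigma_px = blur_sigma_px, seed = as.integer(seed)),
    class = "phantom_spec")
}

# truncated normal by rejection
rtnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    v <- stats::rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
}

# linear indices of raster pixels inside a rotated ellipse
ellipse_pixels <- function(cx, cy, A, B, theta, dims) {
  rmax <- max(A, B)
  cs <- max(1L, floor(cx - rmax)):min(dims[2], ceiling(cx + rmax))
  rs <- max(1L, floor(cy - rmax)):min(dims[1], ceiling(cy + rmax))
  if (!length(cs) || !length(rs)) return(integer())
  cc <- rep(cs, each = length(rs)); rr <- rep(rs, times = length(cs))
  dx <- cc - cx; dy <- rr - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / A)^2 + (v / B)^2 <= 1
  rc_to_idx(rr[keep], cc[keep], dims[1])
}

# 4-connected boundary pixels of a pixel set
boundary_pixels <- function(idx, dims) {
  m <- matrix(FALSE, dims[1], dims[2]); m[idx] <- TRUE
  rc <- idx_to_rc(idx, dims[1])
  on_border <- rc[, 1] == 1L | rc[, 1] == dims[1] |
    rc[, 2] == 1L | rc[, 2] == dims[2]
  inside <- !on_border
  r <- rc[inside, 1]; c <- rc[inside, 2]
  nr <- dims[1]
  full <- m[rc_to_idx(r - 1L, c, nr)] & m[rc_to_idx(r + 1L, c, nr)] &
    m[rc_to_idx(r, c - 1L, nr)] & m[rc_to_idx(r, c + 1L, nr)]
  c(idx[on_border], idx[inside][!full])
}

#' Generate a synthetic TEM phantom with exact ground truth
#'
#' Places non-overlapping fibres by rejection sampling, paints the image
#' (myelin ring, tongue crescent, membrane line, axoplasm, optional
#' mitochondria, unmyelinated axons), applies Gaussian blur plus additive
#' noise clipped to `[0, 1]`, and returns the image together with the
#' ground-truth instance maps, semantic mask, an idealised probability
#' stack, and a truth table whose areas and g-ratios come from the
#' generating ellipse geometry (not from the rasters).
#'
#' @param spec A [phantom_spec()].
#' @param prob_softness_sigma_px Softness of the idealised probability
#'   stack (see [ideal_probabilities()]).
#' @return A list of class `phantom` with elements `image`, `gt_axon`,
#'   `gt_inner`, `gt_fibre`, `gt_semantic`, `ideal_probs`, `truth_table`,
#'   `paint` and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(),
                             prob_softness_sigma_px = 0.7) {
  stopifnot(inherits(spec, "phantom_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  n <- spec$image_size_px
  dims <- c(n, n)
  margin <- 4
  clearance <- 2

  placed <- list()
  centres <- matrix(numeric(), ncol = 3)   # cx, cy, packing radius
  try_place <- function(rad) {
    for (i in seq_len(300L)) {
      cx <- stats::runif(1, margin + rad + 1, n - margin - rad)
      cy <- stats::runif(1, margin + rad + 1, n - margin - rad)
      if (!nrow(centres) ||
          all(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) >
              centres[, 3] + rad + clearance)) {
        return(c(cx, cy))
      }
    }
    NULL
  }

  for (k in seq_len(spec$n_fibres)) {
    r <- min(max(stats::rlnorm(1, spec$axon_radius$meanlog,
                               spec$axon_radius$sdlog),
                 spec$axon_radius$min), spec$axon_radius$max)
    q <- stats::runif(1, 1, 2)
    a <- r * sqrt(q); b <- r / sqrt(q)
    theta <- stats::runif(1, 0, pi)
    g <- rtnorm1(spec$target_g_myelin$mean, spec$target_g_myelin$sd,
                 spec$target_g_myelin$lo, spec$target_g_myelin$hi)
    tf <- min(stats::rbeta(1, spec$tongue_fraction$a, spec$tongue_fraction$b),
              spec$tongue_fraction$max)
    s <- 1 / sqrt(1 - tf)
    pack_rad <- s * a / g
    ctr <- try_place(pack_rad)
    if (is.null(ctr)) next
    centres <- rbind(centres, c(ctr, pack_rad))
    sgn <- sample(c(-1, 1), 1)
    placed[[length(placed) + 1L]] <- list(
      kind = "fibre", cx = ctr[1], cy = ctr[2], a = a, b = b, theta = theta,
      g = g, tf = tf, s = s, sgn = sgn,
      mito = stats::runif(1) < spec$p_mitochondria)
  }
  n_um <- stats::rbinom(1, spec$n_fibres, spec$p_unmyelinated)
  for (k in seq_len(n_um)) {
    r <- min(max(stats::rlnorm(1, spec$axon_radius$meanlog - 0.3,
                               spec$axon_radius$sdlog), 4),
             spec$axon_radius$max)
    q <- stats::runif(1, 1, 2)
    a <- r * sqrt(q); b <- r / sqrt(q)
    theta <- stats::runif(1, 0, pi)
    ctr <- try_place(a)
    if (is.null(ctr)) next
    centres <- rbind(centres, c(ctr, a))
    placed[[length(placed) + 1L]] <- list(
      kind = "unmyelinated", cx = ctr[1], cy = ctr[2], a = a, b = b,
      theta = theta)
  }

  paint <- matrix(0L, n, n)
  gt_axon <- matrix(0L, n, n); gt_inner <- matrix(0L, n, n)
  gt_fibre <- matrix(0L, n, n)
  truth <- list()
  fid <- 0L
  for (obj in placed) {
    if (obj$kind == "unmyelinated") {
      axn <- ellipse_pixels(obj$cx, obj$cy, obj$a, obj$b, obj$theta, dims)
      paint[axn] <- 1L
      paint[boundary_pixels(axn, dims)] <- 3L
      next
    }
    fid <- fid + 1L
    s <- obj$s
    # inner ellipse centred at (cx, cy); axon offset along the major axis
    # until internally tangent, carving the tongue crescent
    d <- (s - 1) * obj$a * obj$sgn
    ax_cx <- obj$cx + d * cos(obj$theta)
    ax_cy <- obj$cy + d * sin(obj$theta)
    fib <- ellipse_pixels(obj$cx, obj$cy, s * obj$a / obj$g,
                          s * obj$b / obj$g, obj$theta, dims)
    inn <- ellipse_pixels(obj$cx, obj$cy, s * obj$a, s * obj$b, obj$theta,
                          dims)
    axn <- ellipse_pixels(ax_cx, ax_cy, obj$a, obj$b, obj$theta, dims)
    inn <- union(inn, axn)       # guard against 1-px rasterisation slivers
    fib <- union(fib, inn)
    gt_fibre[fib] <- fid; gt_inner[inn] <- fid; gt_axon[axn] <- fid
    paint[fib] <- 4L
    paint[setdiff(inn, axn)] <- 2L
    paint[axn] <- 1L
    paint[boundary_pixels(axn, dims)] <- 3L
    if (isTRUE(obj$mito)) {
      ma <- max(1.5, obj$b / 4); mb <- max(1.2, obj$b / 6)
      mtheta <- stats::runif(1, 0, pi)
      off <- stats::runif(1, 0, max(0, obj$b - ma - 3))
      mang <- stats::runif(1, 0, 2 * pi)
      mito <- ellipse_pixels(ax_cx + off * cos(mang), ax_cy + off * sin(mang),
                             ma, mb, mtheta, dims)
      mito <- mito[paint[mito] == 1L]   # keep strictly inside the axoplasm
      paint[mito] <- 5L
    }
    a_axon <- pi * obj$a * obj$b * spec$pixel_size_um^2
    a_inner <- a_axon * s^2
    a_fibre <- a_inner / obj$g^2
    truth[[fid]] <- tibble::tibble(
      fibre_id = fid, cx = obj$cx, cy = obj$cy,
      axon_semi_major_px = obj$a, axon_semi_minor_px = obj$b,
      angle = obj$theta, tongue_fraction = obj$tf,
      area_axon_um2 = a_axon, area_inner_um2 = a_inner,
      area_fibre_um2 = a_fibre,
      area_inner_tongue_um2 = a_inner - a_axon,
      g_myelin = obj$g, g_axon = obj$g * sqrt(1 - obj$tf))
  }
  truth_table <- if (length(truth)) dplyr::bind_rows(truth) else {
    tibble::tibble(fibre_id = integer(), cx = numeric(), cy = numeric(),
                   axon_semi_major_px = numeric(),
                   axon_semi_minor_px = numeric(), angle = numeric(),
                   tongue_fraction = numeric(), area_axon_um2 = numeric(),
                   area_inner_um2 = numeric(), area_fibre_um2 = numeric(),
                   area_inner_tongue_um2 = numeric(), g_myelin = numeric(),
                   g_axon = numeric())
  }

  lv <- spec$intensity_levels
  img <- matrix(lv[["extracellular"]], n, n)
  img[paint == 1L] <- lv[["axoplasm"]]
  img[paint == 2L] <- lv[["tongue"]]
  img[paint == 3L] <- lv[["membrane"]]
  img[paint == 4L] <- lv[["myelin"]]
  img[paint == 5L] <- lv[["mitochondria"]]
  if (spec$blur_sigma_px > 0) img <- filter_gaussian(img, spec$blur_sigma_px)
  if (spec$noise_sd > 0) img <- img + stats::rnorm(n * n, 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 1)

  semantic <- matrix(0L, n, n)
  semantic[gt_fibre > 0L] <- 3L
  semantic[gt_inner > 0L] <- 2L
  semantic[gt_axon > 0L] <- 1L
  gt_semantic <- semantic_mask(semantic, spec$pixel_size_um)

  structure(
    list(image = image2d(img, spec$pixel_size_um),
         gt_axon = instance_map(gt_axon, "axon", spec$pixel_size_um),
         gt_inner = instance_map(gt_inner, "inner_region",
                                 spec$pixel_size_um),
         gt_fibre = instance_map(gt_fibre, "fibre", spec$pixel_size_um),
         gt_semantic = gt_semantic,
         ideal_probs = ideal_probabilities(gt_semantic,
                                           prob_softness_sigma_px),
         truth_table = truth_table,
         paint = paint, spec = spec),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d x %d px, %d myelinated fibres, seed %d\n",
              nrow(x$image$pixels), ncol(x$image$pixels),
              nrow(x$truth_table), x$spec$seed))
  invisible(x)
}

#' Idealised probability stack from a semantic mask
#'
#' One-hot encodes myelin, axoplasm (axon plus inner tongue) and
#' membrane-and-background, then blurs each channel and renormalises so
#' channels sum to one.  The membrane channel additionally covers a thin
#' band (half-width `membrane_halfwidth_px`) around the axolemma — the
#' interface between the axon and the surrounding tongue/myelin — inside
#' the inner region, emulating the widened membrane response a trained
#' pixel classifier produces around a 1-px membrane.
#'
#' @param semantic A [semantic_mask()].
#' @param softness_sigma_px Gaussian blur applied to each channel
#'   (0 = crisp one-hot).
#' @param membrane_halfwidth_px Half-width of the axolemma band in px.
#' @return A [prob_stack()].
#' @export
ideal_probabilities <- function(semantic, softness_sigma_px = 0.7,
                                membrane_halfwidth_px = 1L) {
  stopifnot(inherits(semantic, "semantic_mask"))
  lab <- semantic$labels
  dims <- dim(lab)
  myel <- lab == 3L
  axo <- lab == 1L | lab == 2L
  memb <- lab == 0L
  if (membrane_halfwidth_px >= 0L && any(lab == 1L)) {
    axon <- lab == 1L
    other <- lab == 2L | lab == 3L
    grown <- matrix(as.numeric(EBImage::dilate(
      other * 1, EBImage::makeBrush(3L, "box"))) > 0.5, dims[1], dims[2])
    interface <- axon & grown
    if (membrane_halfwidth_px > 0L && any(interface)) {
      band <- matrix(as.numeric(EBImage::dilate(
        interface * 1,
        EBImage::makeBrush(2L * membrane_halfwidth_px + 1L, "box"))) > 0.5,
        dims[1], dims[2])
    } else {
      band <- interface
    }
    band <- band & (lab == 1L | lab == 2L)   # stay inside the inner region
    memb <- memb | band
    axo <- axo & !band
  }
  p <- array(0, c(dims[1], dims[2], 3))
  p[, , 1] <- myel * 1; p[, , 2] <- axo * 1; p[, , 3] <- memb * 1
  if (softness_sigma_px > 0) {
    for (k in 1:3) p[, , k] <- pmin(pmax(
      filter_gaussian(p[, , k], softness_sigma_px), 0), 1)
  }
  prob_stack(p, semantic$pixel_size_um, renormalise = TRUE)
}

#' Randomly corrupt a probability stack
#'
#' Re-draws the class assignment at a fraction of pixels uniformly at
#' random (taking the current argmax as the class map), re-encodes
#' one-hot, optionally blurs and renormalises.  Used to stress-test the
#' staged pipeline against classifier noise.
#'
#' @param probs A [prob_stack()].
#' @param flip_rate Fraction of pixels to re-draw, in `[0, 0.5)`.
#' @param blur_sigma_px Softening blur after flipping.
#' @param seed Integer seed.
#' @return A [prob_stack()].
#' @export
perturb_probabilities <- function(probs, flip_rate = 0.1, blur_sigma_px = 0,
                                  seed = 1L) {
  stopifnot(inherits(probs, "prob_stack"), flip_rate >= 0, flip_rate < 0.5)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  cls <- argmax_channel(probs)
  npx <- length(cls)
  n_flip <- round(flip_rate * npx)
  if (n_flip > 0) {
    at <- sample.int(npx, n_flip)
    cls[at] <- sample.int(3L, n_flip, replace = TRUE)
  }
  d <- dim(probs$p)
  p <- array(0, d)
  for (k in 1:3) p[, , k] <- (cls == k) * 1
  if (blur_sigma_px > 0) {
    for (k in 1:3) p[, , k] <- pmin(pmax(
      filter_gaussian(p[, , k], blur_sigma_px), 0), 1)
  }
  prob_stack(p, probs$pixel_size_um, renormalise = TRUE)
}

#' Sample sparse training scribbles from a phantom
#'
#' Draws up to `n_per_class` pixels per pixel class (compact myelin,
#' axoplasm, membrane, mitochondria) from the phantom's paint map,
#' mimicking the sparse scribble annotation a user would provide.
#'
#' @param phantom A [generate_phantom()] result.
#' @param n_per_class Pixels per class (default 150).
#' @param seed Integer seed.
#' @return Integer scribble raster (0 unlabelled, 1-4 class codes).
#' @export
sample_scribbles <- function(phantom, n_per_class = 150L, seed = 1L) {
  stopifnot(inherits(phantom, "phantom"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  paint <- phantom$paint
  scrib <- matrix(0L, nrow(paint), ncol(paint))
  pools <- list(`1` = which(paint == 4L),
                `2` = which(paint == 1L | paint == 2L),
                `3` = which(paint == 3L),
                `4` = which(paint == 5L))
  for (code in names(pools)) {
    pool <- pools[[code]]
    if (!length(pool)) next
    take <- pool[sample.int(length(pool), min(n_per_class, length(pool)))]
    scrib[take] <- as.integer(code)
  }
  scrib
}

#' Object-classifier training data from a phantom
#'
#' Extracts axoplasm candidates from the phantom's idealised
#' probabilities, computes their features, and labels each candidate by
#' maximal overlap with the ground truth: axon candidates are split into
#' large/small at the median ground-truth axon equivalent diameter,
#' tongue candidates are labelled `inner_tongue`, and candidates covering
#' neither are left unlabelled (`NA`), as they would be during
#' interactive training.
#'
#' @param phantom A [generate_phantom()] result.
#' @param probs Optional probability stack (defaults to the phantom's
#'   idealised stack).
#' @return List with `features` (with a `true_class` column) and the
#'   candidate `map`.
#' @export
phantom_object_training <- function(phantom, probs = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  if (is.null(probs)) probs <- phantom$ideal_probs
  cand <- axoplasm_candidates(probs)
  feats <- object_feature_table(cand, phantom$image)
  if (!nrow(feats)) {
    feats$true_class <- character()
    return(list(features = feats, map = cand))
  }
  axon_lab <- phantom$gt_axon$labels
  tongue <- phantom$gt_inner$labels > 0L & axon_lab == 0L
  ax_areas <- tabulate(axon_lab[axon_lab > 0L])
  med_d <- stats::median(2 * sqrt(ax_areas[ax_areas > 0] / pi))
  px_sets <- split_label_pixels(cand$labels)
  feats$true_class <- vapply(feats$label, function(l) {
    idx <- px_sets[[as.character(l)]]
    n_ax <- sum(axon_lab[idx] > 0L)
    n_tg <- sum(tongue[idx])
    if (n_ax < length(idx) / 2 && n_tg < length(idx) / 2) return(NA_character_)
    if (n_ax >= n_tg) {
      if (2 * sqrt(length(idx) / pi) >= med_d) "axon_large" else "axon_small"
    } else "inner_tongue"
  }, character(1))
  list(features = feats, map = cand)
}
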