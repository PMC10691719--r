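#' Circle-equivalent diameter
#'
#' Diameter of the circle with the given area: `2 * sqrt(area / pi)`.
#' This is the convention used for all g-ratio computations: axon, inner
#' region and fibre areas are assimilated to circles.
#'
#' @param area_um2 Area (micrometres squared), >= 0.
#' @return Diameter in micrometres.
#' @export
circle_equivalent_diameter <- function(area_um2) {
  if (any(area_um2 < 0)) stop("area must be non-negative", call. = FALSE)
  2 * sqrt(area_um2 / pi)
}

#' Build the fibre -> inner region -> axon hierarchy
#'
#' Post-processes the three candidate sets into one consistent hierarchy:
#'
#' 1. inner-region and fibre regions are reduced to their largest
#'    connected component (axons may remain composite);
#' 2. containment is enforced by clipping: `inner := inner & fibre`,
#'    `axon := axon & inner`;
#' 3. an entry without an axon optionally duplicates its inner region as
#'    the axon (flagged), the convention for fibres whose inner tongue
#'    has shrunk beyond detection;
#' 4. axons attach to the inner region they maximally overlap (ties to
#'    the lower inner label); entries are keyed by fibre label and
#'    flagged when the fibre touches the outermost row/column.
#'
#' @param inner Selected inner-region candidates (tibble) or an
#'   [instance_map()].
#' @param fibres Fibre [instance_map()] (labels match the seeds).
#' @param axons Selected axon candidates (tibble) or an [instance_map()];
#'   may be `NULL`.
#' @param duplicate_inner_as_axon Duplicate the inner region when no axon
#'   was selected (default `TRUE`).
#' @return An object of class `fibre_hierarchy`: a tibble with columns
#'   `fibre_id`, pixel list-columns `fibre_px`, `inner_px`, `axon_px`,
#'   and flags `axon_duplicated`, `border_flag`.
#' @export
build_hierarchy <- function(inner, fibres, axons = NULL,
                            duplicate_inner_as_axon = TRUE) {
  stopifnot(inherits(fibres, "instance_map"))
  dims <- dim(fibres$labels)
  ps <- fibres$pixel_size_um
  inner_sets <- hierarchy_pixel_sets(inner, dims)
  fibre_sets <- split_label_pixels(fibres$labels)
  axon_sets <- hierarchy_pixel_sets(axons, dims)

  # largest component only (rule applies to inner and fibre)
  fibre_sets <- lapply(fibre_sets, largest_component, dims = dims)
  inner_sets <- lapply(inner_sets, largest_component, dims = dims)

  fibre_ids <- sort(as.integer(names(fibre_sets)))
  if (!length(fibre_ids)) {
    return(new_fibre_hierarchy(empty_hierarchy_tbl(), dims, ps))
  }

  # inner -> fibre by maximal overlap (in the staged pipeline labels
  # already coincide; overlap assignment also covers curated inputs)
  fibre_lab <- matrix(0L, dims[1], dims[2])
  for (f in fibre_ids) fibre_lab[fibre_sets[[as.character(f)]]] <- f
  inner_of <- stats::setNames(vector("list", length(fibre_ids)),
                              as.character(fibre_ids))
  for (nm in names(inner_sets)) {
    idx <- inner_sets[[nm]]
    at <- fibre_lab[idx]
    ov <- tabulate(at[at > 0L], nbins = max(fibre_ids))
    if (!length(ov) || max(ov) == 0L) next
    f <- as.character(which.max(ov))
    clipped <- idx[at == as.integer(f)]
    if (is.null(inner_of[[f]]) || length(clipped) > length(inner_of[[f]])) {
      inner_of[[f]] <- clipped
    }
  }

  # axon -> inner by maximal overlap; composite axons union per inner
  inner_lab <- matrix(0L, dims[1], dims[2])
  for (f in fibre_ids) {
    if (!is.null(inner_of[[as.character(f)]])) {
      inner_lab[inner_of[[as.character(f)]]] <- f
    }
  }
  axon_of <- stats::setNames(vector("list", length(fibre_ids)),
                             as.character(fibre_ids))
  for (nm in names(axon_sets)) {
    idx <- axon_sets[[nm]]
    at <- inner_lab[idx]
    ov <- tabulate(at[at > 0L], nbins = max(fibre_ids))
    if (!length(ov) || max(ov) == 0L) next
    f <- which.max(ov)
    clipped <- idx[at == f]        # axon never breaks through the inner region
    if (!length(clipped)) {
      warning("axon candidate ", nm, " empties after clipping; dropped")
      next
    }
    f <- as.character(f)
    axon_of[[f]] <- sort(unique(c(axon_of[[f]], clipped)))
  }

  rows <- lapply(fibre_ids, function(f) {
    key <- as.character(f)
    fib <- fibre_sets[[key]]
    inn <- inner_of[[key]]
    if (is.null(inn)) inn <- integer()
    axn <- axon_of[[key]]
    dup <- FALSE
    if (is.null(axn) || !length(axn)) {
      if (duplicate_inner_as_axon && length(inn)) {
        axn <- inn
        dup <- TRUE
      } else {
        axn <- integer()
      }
    }
    tibble::tibble(fibre_id = f, fibre_px = list(sort(fib)),
                   inner_px = list(sort(inn)), axon_px = list(axn),
                   axon_duplicated = dup,
                   border_flag = touches_border(fib, dims))
  })
  new_fibre_hierarchy(dplyr::bind_rows(rows), dims, ps)
}

hierarchy_pixel_sets <- function(x, dims) {
  if (is.null(x)) return(list())
  if (inherits(x, "instance_map")) {
    stopifnot(identical(dim(x$labels), dims))
    return(split_label_pixels(x$labels))
  }
  sel <- x[x$state == "selected", ]
  stats::setNames(sel$pixels, sel$label)
}

empty_hierarchy_tbl <- function() {
  tibble::tibble(fibre_id = integer(), fibre_px = list(), inner_px = list(),
                 axon_px = list(), axon_duplicated = logical(),
                 border_flag = logical())
}

new_fibre_hierarchy <- function(tbl, dims, pixel_size_um) {
  attr(tbl, "dims") <- as.integer(dims)
  attr(tbl, "pixel_size_um") <- as.numeric(pixel_size_um)
  class(tbl) <- c("fibre_hierarchy", setdiff(class(tbl), "fibre_hierarchy"))
  tbl
}

#' @export
`[.fibre_hierarchy` <- function(x, ...) {
  dims <- attr(x, "dims"); ps <- attr(x, "pixel_size_um")
  new_fibre_hierarchy(NextMethod(), dims, ps)
}

#' @export
print.fibre_hierarchy <- function(x, ...) {
  cat(sprintf("<fibre_hierarchy> %d fibres, %d x %d px raster\n",
              nrow(x), attr(x, "dims")[1], attr(x, "dims")[2]))
  NextMethod()
}

#' Per-fibre myelin morphometry
#'
#' Areas are pixel counts times the squared pixel size; diameters are
#' circle-equivalent; the myelin g-ratio is `d_inner / d_fibre`
#' (equivalently `sqrt(area_inner / area_fibre)`), the axon g-ratio is
#' `d_axon / d_fibre`, and the tongue index is their difference — zero
#' when the inner tongue is absent.  Fibre eccentricity comes from the
#' fibre region's second central moments (0 = circle).  Border-touching
#' fibres are measured and flagged, never dropped here; exclusion is the
#' evaluation pairing's job.
#'
#' @param h A [build_hierarchy()] result.
#' @return A tibble with one row per fibre.
#' @export
measure_fibres <- function(h) {
  stopifnot(inherits(h, "fibre_hierarchy"))
  ps2 <- attr(h, "pixel_size_um")^2
  dims <- attr(h, "dims")
  if (!nrow(h)) {
    return(tibble::tibble(
      fibre_id = integer(), area_axon_um2 = numeric(),
      area_inner_um2 = numeric(), area_fibre_um2 = numeric(),
      area_inner_tongue_um2 = numeric(), area_myelin_um2 = numeric(),
      d_axon_um = numeric(), d_inner_um = numeric(), d_fibre_um = numeric(),
      g_myelin = numeric(), g_axon = numeric(), tongue_index = numeric(),
      eccentricity_fibre = numeric(), border_flag = logical()))
  }
  purrr::pmap_dfr(
    list(h$fibre_id, h$fibre_px, h$inner_px, h$axon_px, h$border_flag),
    function(id, fib, inn, axn, border) {
      a_f <- length(fib) * ps2
      if (a_f == 0) stop("fibre ", id, " has zero area", call. = FALSE)
      a_i <- length(inn) * ps2
      a_a <- length(axn) * ps2
      d_f <- circle_equivalent_diameter(a_f)
      d_i <- circle_equivalent_diameter(a_i)
      d_a <- circle_equivalent_diameter(a_a)
      tibble::tibble(
        fibre_id = id,
        area_axon_um2 = a_a, area_inner_um2 = a_i, area_fibre_um2 = a_f,
        area_inner_tongue_um2 = a_i - a_a, area_myelin_um2 = a_f - a_i,
        d_axon_um = d_a, d_inner_um = d_i, d_fibre_um = d_f,
        g_myelin = d_i / d_f, g_axon = d_a / d_f,
        tongue_index = (d_i - d_a) / d_f,
        eccentricity_fibre = moment_eccentricity(idx_to_rc(fib, dims[1])),
        border_flag = border)
    })
}

#' @exportS3Method generics::tidy
tidy.fibre_hierarchy <- function(x, ...) measure_fibres(x)

#' Semantic mask from a hierarchy
#'
#' Paints compact myelin as `fibre - inner`, inner tongue as
#' `inner - axon`, axon as `axon`; everything else is background.
#'
#' @param h A [build_hierarchy()] result.
#' @return A [semantic_mask()] on the hierarchy's raster frame.
#' @export
semantic_from_hierarchy <- function(h) {
  stopifnot(inherits(h, "fibre_hierarchy"))
  dims <- attr(h, "dims")
  lab <- matrix(0L, dims[1], dims[2])
  codes <- semantic_codes()
  for (i in seq_len(nrow(h))) {
    if (any(lab[h$fibre_px[[i]]] != 0L)) {
      stop("overlapping fibres violate the hierarchy invariant", call. = FALSE)
    }
    lab[h$fibre_px[[i]]] <- codes[["compact_myelin"]]
    lab[h$inner_px[[i]]] <- codes[["inner_tongue"]]
    lab[h$axon_px[[i]]] <- codes[["axon"]]
  }
  semantic_mask(lab, attr(h, "pixel_size_um"))
}

#' Instance maps of a hierarchy's components
#'
#' @param h A [build_hierarchy()] result.
#' @return Named list of three [instance_map()]s (`inner_region`, `fibre`,
#'   `axon`) keyed by fibre id.
#' @export
hierarchy_maps <- function(h) {
  stopifnot(inherits(h, "fibre_hierarchy"))
  dims <- attr(h, "dims")
  ps <- attr(h, "pixel_size_um")
  mk <- function(col, kind) {
    lab <- matrix(0L, dims[1], dims[2])
    for (i in seq_len(nrow(h))) lab[h[[col]][[i]]] <- h$fibre_id[i]
    instance_map(lab, kind, ps)
  }
  list(inner_region = mk("inner_px", "inner_region"),
       fibre = mk("fibre_px", "fibre"),
       axon = mk("axon_px", "axon"))
}
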