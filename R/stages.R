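# Candidate (ROI) sets are tibbles with one row per candidate:
#   label (int), stage (chr), state ("selected"/"rejected"), pixels
#   (list-column of linear pixel indices), plus stage-specific columns.
# Raster geometry travels in attributes `dims` and `pixel_size_um`.

new_roi_candidates <- function(tbl, dims, pixel_size_um) {
  attr(tbl, "dims") <- as.integer(dims)
  attr(tbl, "pixel_size_um") <- as.numeric(pixel_size_um)
  class(tbl) <- c("roi_candidates", setdiff(class(tbl), "roi_candidates"))
  tbl
}

#' @export
`[.roi_candidates` <- function(x, ...) {
  dims <- attr(x, "dims"); ps <- attr(x, "pixel_size_um")
  mm <- attr(x, "myelin_mask")
  out <- NextMethod()
  out <- new_roi_candidates(out, dims, ps)
  attr(out, "myelin_mask") <- mm
  out
}

roi_dims <- function(x) attr(x, "dims")

#' Convert a candidate set to an instance label map
#'
#' @param candidates A candidate tibble (e.g. from [stage1_inner_regions()]).
#' @param component_kind Kind recorded on the resulting [instance_map()].
#' @param selected_only Use only candidates in the `"selected"` state.
#' @return An [instance_map()].
#' @export
candidates_to_map <- function(candidates, component_kind,
                              selected_only = TRUE) {
  dims <- roi_dims(candidates)
  lab <- matrix(0L, dims[1], dims[2])
  keep <- if (selected_only) candidates$state == "selected" else TRUE
  tbl <- candidates[keep, ]
  for (i in seq_len(nrow(tbl))) lab[tbl$pixels[[i]]] <- tbl$label[i]
  instance_map(lab, component_kind, attr(candidates, "pixel_size_um"))
}

#' Stage 1: detect inner regions from the myelin probability channel
#'
#' The myelin mask (per-pixel argmax of the probability stack, optionally
#' closed with a radius-1 structuring element) is inverted and its
#' 8-connected components become inner-region candidates.  A component is
#' *selected* when it (a) does not touch the image border, (b) has an area
#' within `[min_area_px, max_area_fraction * image area]`, and (c) has a
#' mean axoplasm probability of at least `axoplasm_gate`.  All other
#' components are kept in the *rejected* state so curation can recover
#' them; nothing is silently discarded.
#'
#' @param prob A [prob_stack()].
#' @param min_area_px Minimum selected component area (default 50).
#' @param max_area_fraction Maximum area as a fraction of the image
#'   (default 0.05).
#' @param axoplasm_gate Minimum mean axoplasm probability (default 0.4).
#' @param close_radius Radius of the closing applied to the myelin mask
#'   before inversion; 0 disables (default 1).
#' @return A candidate tibble (stage `"inner_region"`) carrying the binary
#'   myelin mask in attribute `myelin_mask`.
#' @export
stage1_inner_regions <- function(prob, min_area_px = 50L,
                                 max_area_fraction = 0.05,
                                 axoplasm_gate = 0.4, close_radius = 1L) {
  stopifnot(inherits(prob, "prob_stack"))
  dims <- dim(prob)
  myelin <- argmax_channel(prob) == 1L
  if (close_radius > 0L) {
    brush <- EBImage::makeBrush(2L * close_radius + 1L, "box")
    myelin <- matrix(
      as.logical(EBImage::closing(myelin * 1, brush) > 0.5), dims[1], dims[2])
  }
  lab <- label_components(!myelin, 8)
  px_sets <- split_label_pixels(lab)
  axo <- prob$p[, , "axoplasm"]
  max_area <- max_area_fraction * prod(dims)
  rows <- purrr::imap(px_sets, function(idx, l) {
    ok <- !touches_border(idx, dims) &&
      length(idx) >= min_area_px && length(idx) <= max_area &&
      mean(axo[idx]) >= axoplasm_gate
    tibble::tibble(label = as.integer(l), stage = "inner_region",
                   state = if (ok) "selected" else "rejected",
                   pixels = list(idx))
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(label = integer(), stage = character(),
                   state = character(), pixels = list())
  }
  out <- new_roi_candidates(out, dims, prob$pixel_size_um)
  attr(out, "myelin_mask") <- myelin
  out
}

# level-synchronous multi-source BFS flood: each domain pixel joins the
# seed with the smallest 8-connected geodesic distance; equidistant ties
# go to the lower seed label
flood_from_seeds <- function(seed_lab, domain) {
  nr <- nrow(seed_lab); nc <- ncol(seed_lab)
  lab <- seed_lab
  lab[!domain & lab == 0L] <- -1L   # outside flood domain
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  big <- .Machine$integer.max
  repeat {
    cand <- matrix(big, nr, nc)
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      sh <- matrix(big, nr, nc)
      rs <- max(1, 1 + dr):min(nr, nr + dr)
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      src <- lab[rs - dr, cs - dc, drop = FALSE]
      src[src <= 0L] <- big
      sh[rs, cs] <- src
      cand <- pmin(cand, sh)
    }
    newly <- lab == 0L & cand < big
    if (!any(newly)) break
    lab[newly] <- cand[newly]
  }
  lab[lab < 0L] <- 0L
  lab
}

#' Stage 2: expand inner-region seeds to fill the myelin mask
#'
#' Marker-controlled region growing with a uniform geodesic cost: every
#' myelin pixel that is 8-connected to at least one seed within
#' (myelin mask plus seeds) is assigned to the seed with the smallest
#' geodesic distance (ties to the lower seed label).  Each fibre is its
#' seed (inner region) plus the myelin territory it claims; myelin
#' unreachable from any seed stays background — so a missed seed lets the
#' surrounding fibres' myelin overflow or go unclaimed, exactly the
#' failure mode that seed curation repairs.
#'
#' @param inner Inner-region candidates from [stage1_inner_regions()]
#'   (only `"selected"` rows seed the expansion), or an [instance_map()]
#'   of seeds.
#' @param myelin_mask Logical matrix of myelin pixels; defaults to the
#'   mask attached by Stage 1.
#' @return An [instance_map()] of kind `"fibre"` whose labels equal the
#'   seed labels.
#' @export
stage2_fibres <- function(inner, myelin_mask = NULL) {
  if (inherits(inner, "instance_map")) {
    seed_lab <- inner$labels
    dims <- dim(seed_lab)
    ps <- inner$pixel_size_um
  } else {
    dims <- roi_dims(inner)
    ps <- attr(inner, "pixel_size_um")
    if (is.null(myelin_mask)) myelin_mask <- attr(inner, "myelin_mask")
    seed_lab <- candidates_to_map(inner, "inner_region")$labels
  }
  stopifnot(!is.null(myelin_mask), identical(dim(myelin_mask), dims))
  if (all(seed_lab == 0L)) {
    return(instance_map(matrix(0L, dims[1], dims[2]), "fibre", ps))
  }
  domain <- (myelin_mask | seed_lab > 0L)
  out <- flood_from_seeds(seed_lab, domain)
  instance_map(out, "fibre", ps)
}

#' Stage 3: select axons among classified candidates
#'
#' An object predicted `axon_large`/`axon_small` is *selected* when at
#' least `overlap_fraction` of its area lies inside a single inner region,
#' and is assigned to that fibre (overlap ties go to the lower inner
#' label).  Candidates classified `inner_tongue` that touch an inner
#' region are kept as *rejected* (curable); objects not meeting their gate
#' are dropped — they lie outside myelinated fibre cross-sections.  When
#' several axons are selected for one inner region only the largest is
#' kept; the rest are demoted to rejected.
#'
#' @param objects Classified candidate features ([classify_objects()]
#'   output: needs `label` and `predicted_class`).
#' @param candidate_map The [instance_map()] the features were computed
#'   from.
#' @param inner_map Final inner-region [instance_map()] for this image.
#' @param overlap_fraction Minimum fraction of candidate area inside one
#'   inner region (default 0.5).
#' @return A candidate tibble (stage `"axon"`) with a `fibre_id` column.
#' @export
stage3_axons <- function(objects, candidate_map, inner_map,
                         overlap_fraction = 0.5) {
  stopifnot(inherits(candidate_map, "instance_map"),
            inherits(inner_map, "instance_map"))
  dims <- dim(candidate_map$labels)
  px_sets <- split_label_pixels(candidate_map$labels)
  rows <- list()
  for (i in seq_len(nrow(objects))) {
    lab <- objects$label[i]
    cls <- objects$predicted_class[i]
    idx <- px_sets[[as.character(lab)]]
    if (is.null(idx)) next
    inner_at <- inner_map$labels[idx]
    ov <- tabulate(inner_at[inner_at > 0L])
    if (!length(ov) || max(ov) == 0L) next       # outside fibres: drop
    best <- which.max(ov)                         # ties: lower inner label
    frac <- ov[best] / length(idx)
    if (cls %in% c("axon_large", "axon_small")) {
      if (frac < overlap_fraction) next           # weak overlap: drop
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = lab, stage = "axon", state = "selected",
        pixels = list(idx), fibre_id = as.integer(best),
        predicted_class = cls)
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        label = lab, stage = "axon", state = "rejected",
        pixels = list(idx), fibre_id = as.integer(best),
        predicted_class = cls)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(label = integer(), stage = character(),
                   state = character(), pixels = list(),
                   fibre_id = integer(), predicted_class = character())
  }
  # one selected axon per inner region: keep the largest
  sel <- which(out$state == "selected")
  if (length(sel) > 1L) {
    areas <- lengths(out$pixels[sel])
    ord <- sel[order(out$fibre_id[sel], -areas, out$label[sel])]
    dup <- ord[duplicated(out$fibre_id[ord])]
    out$state[dup] <- "rejected"
  }
  new_roi_candidates(out, dims, candidate_map$pixel_size_um)
}

# ---- curation ---------------------------------------------------------------

#' Read a curation-override file
#'
#' JSON with per-stage accept/reject label lists and added polygons, e.g.
#' `{"stage1": {"accept": [3], "reject": [], "add": [[[x,y], ...]]}}`.
#' Polygon coordinates are `(x, y)` pixel positions of the processed
#' image, y increasing downward.
#'
#' @param path Path to the JSON file.
#' @return A named list of per-stage overrides.
#' @export
read_curation <- function(path) {
  jsonlite::fromJSON(path, simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
}

# even-odd (crossing-number) rasterisation of a closed polygon given as an
# n x 2 matrix of (x, y) vertices; returns linear pixel indices
rasterise_polygon <- function(poly, dims) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L || !all(is.finite(poly))) {
    stop("polygon must have at least 3 finite vertices", call. = FALSE)
  }
  if (polygon_self_intersects(poly)) {
    stop("polygon is self-intersecting", call. = FALSE)
  }
  xs <- poly[, 1]; ys <- poly[, 2]
  cmin <- max(1L, floor(min(xs))); cmax <- min(dims[2], ceiling(max(xs)))
  rmin <- max(1L, floor(min(ys))); rmax <- min(dims[1], ceiling(max(ys)))
  if (cmin > cmax || rmin > rmax) return(integer())
  cc <- matrix(rep(cmin:cmax, each = rmax - rmin + 1L),
               nrow = rmax - rmin + 1L)
  rr <- matrix(rep(rmin:rmax, times = cmax - cmin + 1L),
               nrow = rmax - rmin + 1L)
  inside <- matrix(FALSE, nrow(rr), ncol(rr))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
    crosses <- ((y1 > rr) != (y2 > rr)) &
      (cc < (x2 - x1) * (rr - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  rc_to_idx(rr[inside], cc[inside], dims[1])
}

# any non-adjacent edge pair properly intersecting?
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next   # adjacent through the closure
      a <- seg[i, ]; b <- seg[j, ]
      o1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      o2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      o3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      o4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (o1 != o2 && o3 != o4 && all(c(o1, o2, o3, o4) != 0)) return(TRUE)
    }
  }
  FALSE
}

#' Apply a batch curation override to a candidate set
#'
#' Toggles the listed labels to the requested state and rasterises any
#' added polygons (even-odd fill) as new selected candidates with fresh
#' labels.  Unknown labels produce a warning, not an error.
#'
#' @param candidates A candidate tibble.
#' @param override One stage's override list with elements `accept`,
#'   `reject` and `add` (any may be absent).
#' @return The curated candidate tibble.
#' @export
apply_curation <- function(candidates, override) {
  if (is.null(override)) return(candidates)
  dims <- roi_dims(candidates)
  acc <- as.integer(unlist(override$accept))
  rej <- as.integer(unlist(override$reject))
  if (length(intersect(acc, rej))) {
    stop("accept and reject lists overlap: ",
         paste(intersect(acc, rej), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(c(acc, rej), candidates$label)
  if (length(unknown)) {
    warning("curation refers to unknown label(s): ",
            paste(unknown, collapse = ", "))
  }
  candidates$state[candidates$label %in% acc] <- "selected"
  candidates$state[candidates$label %in% rej] <- "rejected"
  polys <- override$add
  if (!is.null(polys) && length(polys)) {
    next_label <- if (nrow(candidates)) max(candidates$label) else 0L
    stage <- if (nrow(candidates)) candidates$stage[1] else "inner_region"
    for (p in polys) {
      idx <- rasterise_polygon(p, dims)
      if (!length(idx)) next
      next_label <- next_label + 1L
      row <- tibble::tibble(label = next_label, stage = stage,
                            state = "selected", pixels = list(idx))
      for (extra in setdiff(names(candidates), names(row))) {
        row[[extra]] <- NA
      }
      candidates <- dplyr::bind_rows(candidates, row[names(candidates)])
    }
  }
  new_roi_candidates(candidates, dims, attr(candidates, "pixel_size_um"))
}

# ---- axon correction --------------------------------------------------------

#' Correct an axon pixel set
#'
#' Optional automatic repair of a predicted axon region.  `fill_holes`
#' fills enclosed background (mitochondria-induced holes); `convex_hull`
#' replaces the region by its convex hull (computed on pixel-cell
#' corners); `closing` applies a morphological closing with a disc of the
#' given radius; `dilate` (the pipeline default) fills holes and then
#' grows the region by a disc — compensating the rim the membrane class
#' shaves off every axon, since the axolemma belongs to the axon but is
#' classified as membrane; downstream hierarchy clipping keeps the grown
#' axon inside its inner region.  All methods are area-non-decreasing.
#'
#' @param pixels Integer vector of linear pixel indices.
#' @param dims Raster dimensions `c(rows, cols)`.
#' @param method One of `"none"`, `"fill_holes"`, `"convex_hull"`,
#'   `"closing"`, `"dilate"`.
#' @param radius Disc radius for `"closing"` / `"dilate"` (default 2).
#' @return The corrected pixel-index set.
#' @export
correct_axon <- function(pixels, dims,
                         method = c("none", "fill_holes", "convex_hull",
                                    "closing", "dilate"),
                         radius = 2L) {
  method <- match.arg(method)
  if (method == "none" || !length(pixels)) return(pixels)
  m <- matrix(0, dims[1], dims[2])
  m[pixels] <- 1
  out <- switch(method,
    fill_holes = which(matrix(as.numeric(EBImage::fillHull(m)),
                              dims[1], dims[2]) > 0.5),
    dilate = {
      filled <- EBImage::fillHull(m)
      dl <- EBImage::dilate(filled, EBImage::makeBrush(2L * radius + 1L,
                                                       "disc"))
      which(matrix(as.numeric(dl), dims[1], dims[2]) > 0.5)
    },
    convex_hull = {
      rc <- idx_to_rc(pixels, dims[1])
      corners <- rbind(
        cbind(rc[, 1] - 0.5, rc[, 2] - 0.5), cbind(rc[, 1] - 0.5, rc[, 2] + 0.5),
        cbind(rc[, 1] + 0.5, rc[, 2] - 0.5), cbind(rc[, 1] + 0.5, rc[, 2] + 0.5))
      h <- grDevices::chull(corners)
      # hull vertices as (x = col, y = row)
      poly <- corners[h, c(2, 1), drop = FALSE]
      union(pixels, rasterise_polygon(poly, dims))
    },
    closing = {
      pad <- radius + 1L
      mp <- matrix(0, dims[1] + 2L * pad, dims[2] + 2L * pad)
      mp[pad + seq_len(dims[1]), pad + seq_len(dims[2])] <- m
      cl <- EBImage::closing(mp, EBImage::makeBrush(2L * radius + 1L, "disc"))
      which(matrix(as.numeric(cl), nrow(mp),
                   ncol(mp))[pad + seq_len(dims[1]),
                             pad + seq_len(dims[2])] > 0.5)
    }
  )
  sort(as.integer(out))
}
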