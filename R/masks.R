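#' Instance label map
#'
#' Integer raster in which each positive value identifies one object
#' (inner region, fibre or axon) and 0 is background.
#'
#' @param labels Non-negative integer matrix.
#' @param component_kind One of `"inner_region"`, `"fibre"`, `"axon"`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `instance_map`.
#' @export
instance_map <- function(labels,
                         component_kind = c("inner_region", "fibre", "axon"),
                         pixel_size_um = 1) {
  component_kind <- match.arg(component_kind)
  if (!is.matrix(labels) || any(labels < 0) || any(labels != round(labels))) {
    stop("`labels` must be a matrix of non-negative integers", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, component_kind = component_kind,
         pixel_size_um = as.numeric(pixel_size_um)),
    class = "instance_map"
  )
}

#' @export
print.instance_map <- function(x, ...) {
  cat(sprintf("<instance_map:%s> %d x %d px, %d objects\n",
              x$component_kind, nrow(x$labels), ncol(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' @export
dim.instance_map <- function(x) dim(x$labels)

#' Semantic segmentation mask
#'
#' Every pixel holds exactly one of the four class codes:
#' 0 background, 1 axon, 2 inner tongue, 3 compact myelin.
#'
#' @param labels Integer matrix with values in `0:3`.
#' @param pixel_size_um Pixel size in micrometres.
#' @return An object of class `semantic_mask`.
#' @export
semantic_mask <- function(labels, pixel_size_um = 1) {
  if (!is.matrix(labels) || !all(labels %in% 0:3)) {
    stop("semantic codes must be 0 (background), 1 (axon), 2 (inner tongue) ",
         "or 3 (compact myelin)", call. = FALSE)
  }
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "semantic_mask"
  )
}

#' Semantic class codes
#'
#' Named integer vector mapping semantic class names to raster codes.
#' @export
semantic_codes <- function() {
  c(background = 0L, axon = 1L, inner_tongue = 2L, compact_myelin = 3L)
}

#' Per-pixel class probability stack
#'
#' A `height x width x 3` array of class probabilities with channels
#' `myelin`, `axoplasm`, `membrane`; channels sum to one at every pixel.
#'
#' @param p Numeric array `[h, w, 3]`.
#' @param pixel_size_um Pixel size in micrometres.
#' @param renormalise If `TRUE`, rescale each pixel's channel vector to sum
#'   to exactly one.
#' @return An object of class `prob_stack`.
#' @export
prob_stack <- function(p, pixel_size_um = 1, renormalise = FALSE) {
  if (!is.array(p) || length(dim(p)) != 3L || dim(p)[3] != 3L) {
    stop("`p` must be a [h, w, 3] array", call. = FALSE)
  }
  if (any(p < -1e-9) || any(p > 1 + 1e-9)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  p[p < 0] <- 0
  p[p > 1] <- 1
  if (renormalise) {
    s <- p[, , 1] + p[, , 2] + p[, , 3]
    s[s == 0] <- 1
    for (k in 1:3) p[, , k] <- p[, , k] / s
  }
  s <- p[, , 1] + p[, , 2] + p[, , 3]
  if (max(abs(s - 1)) > 1e-6) {
    stop("probability channels must sum to 1 per pixel (tolerance 1e-6)",
         call. = FALSE)
  }
  dimnames(p) <- list(NULL, NULL, c("myelin", "axoplasm", "membrane"))
  structure(
    list(p = p, pixel_size_um = as.numeric(pixel_size_um)),
    class = "prob_stack"
  )
}

#' @export
dim.prob_stack <- function(x) dim(x$p)[1:2]

#' Per-pixel most probable class of a probability stack
#'
#' @param prob A [prob_stack()].
#' @return Integer matrix with 1 = myelin, 2 = axoplasm, 3 = membrane.
#'   Ties resolve to the lowest channel index.
#' @export
argmax_channel <- function(prob) {
  stopifnot(inherits(prob, "prob_stack"))
  d <- dim(prob$p)
  flat <- matrix(prob$p, nrow = d[1] * d[2], ncol = d[3])
  matrix(max.col(flat, ties.method = "first"), d[1], d[2])
}

# ---- connected components ---------------------------------------------------

# union-find root lookup (no compression; merge chains stay short)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Label connected components of a binary mask
#'
#' 8-connected labelling built on `EBImage::bwlabel()` (4-connected), with
#' diagonal adjacencies merged by union-find.  Labels are renumbered
#' `1..n` in raster-scan (row-major) order of each component's first
#' pixel, giving a deterministic numbering.
#'
#' @param mask Logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- matrix(as.integer(EBImage::bwlabel(m)), nrow(mask), ncol(mask))
  if (connectivity == 8 && max(lab) > 1L) {
    n <- max(lab)
    parent <- seq_len(n)
    nr <- nrow(lab); nc <- ncol(lab)
    # the two diagonal adjacency directions
    pair_up <- function(a, b) {
      keep <- a > 0L & b > 0L & a != b
      unique(cbind(a[keep], b[keep]))
    }
    prs <- rbind(
      pair_up(lab[-nr, -nc], lab[-1, -1]),   # down-right
      pair_up(lab[-nr, -1], lab[-1, -nc])    # down-left
    )
    if (nrow(prs)) {
      for (i in seq_len(nrow(prs))) {
        ra <- uf_find(parent, prs[i, 1])
        rb <- uf_find(parent, prs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  renumber_raster_order(lab)
}

#' Renumber positive labels in raster-scan order
#'
#' Relabels the positive values of a label matrix to `1..n`, ordered by
#' the row-major position of each label's first pixel.
#'
#' @param lab Integer label matrix.
#' @return Relabelled integer matrix.
#' @export
renumber_raster_order <- function(lab) {
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  nr <- nrow(lab)
  row <- (pos - 1L) %% nr + 1L
  col <- (pos - 1L) %/% nr + 1L
  key <- order(row, col)          # raster scan: rows outer, columns inner
  first_seen <- !duplicated(lab[pos][key])
  old <- lab[pos][key][first_seen]
  map <- integer(max(lab))
  map[old] <- seq_along(old)
  lab[pos] <- map[lab[pos]]
  lab
}

# ---- pixel-set helpers (linear indices, column-major as stored by R) --------

# linear indices of each label in an instance map, as a named list
split_label_pixels <- function(labels) {
  pos <- which(labels > 0L)
  split(pos, labels[pos])
}

# row/col coordinates (1-based) for linear indices
idx_to_rc <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

rc_to_idx <- function(row, col, nr) {
  (col - 1L) * nr + row
}

# largest connected component of a pixel-index set (8-connectivity)
largest_component <- function(idx, dims) {
  if (length(idx) <= 1L) return(idx)
  m <- matrix(FALSE, dims[1], dims[2])
  m[idx] <- TRUE
  lab <- label_components(m, 8)
  tab <- tabulate(lab[idx])
  best <- which.max(tab)   # ties: lowest (raster-first) label
  idx[lab[idx] == best]
}

# does a pixel set touch the outermost row/col?
touches_border <- function(idx, dims) {
  rc <- idx_to_rc(idx, dims[1])
  any(rc[, 1] == 1L | rc[, 1] == dims[1] | rc[, 2] == 1L | rc[, 2] == dims[2])
}
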