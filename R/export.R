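#' Write an instance or semantic label raster as 16-bit TIFF
#'
#' Labels are stored as `value / 65535`, the convention the **tiff**
#' package uses for 16-bit data, so [read_label_tiff()] recovers them
#' exactly (labels up to 65535).
#'
#' @param labels Integer label matrix.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @param component_kind Kind for the reconstructed [instance_map()].
#' @param pixel_size_um Pixel size to attach.
#' @export
read_label_tiff <- function(path, component_kind = "fibre",
                            pixel_size_um = 1) {
  m <- round(tiff::readTIFF(path) * 65535)
  storage.mode(m) <- "integer"
  instance_map(m, component_kind, pixel_size_um)
}

# closed boundary polygons of one pixel set, via contour tracing on a
# zero-padded mask; coordinates (x = col, y = row), y increasing downward
region_polygons <- function(idx, dims) {
  m <- matrix(0, dims[1] + 2L, dims[2] + 2L)
  rc <- idx_to_rc(idx, dims[1])
  m[cbind(rc[, 1] + 1L, rc[, 2] + 1L)] <- 1
  cl <- grDevices::contourLines(x = seq_len(dims[1] + 2L) - 1L,
                                y = seq_len(dims[2] + 2L) - 1L,
                                z = m, levels = 0.5)
  lapply(cl, function(seg) cbind(x = seg$y, y = seg$x))
}

#' Export segmentation outputs
#'
#' Writes, per image stem: 16-bit TIFF label masks (`<stem>_axon.tif`,
#' `<stem>_inner.tif`, `<stem>_fibre.tif`), the semantic mask
#' (`<stem>_semantic.tif`, codes 0-3), a `results.csv` morphometry table
#' keyed by fibre id, optional GeoJSON boundary polygons
#' (`<stem>_rois.geojson`, pixel coordinates, y downward) and an overlay
#' PNG for visual QC.
#'
#' @param hierarchy A [build_hierarchy()] result.
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem (default `"image"`).
#' @param img Optional [image2d()] for the overlay background.
#' @param formats Subset of `c("tiff", "csv", "geojson", "png")`.
#' @return Tibble manifest of written files.
#' @export
export_outputs <- function(hierarchy, out_dir, stem = "image", img = NULL,
                           formats = c("tiff", "csv", "geojson", "png")) {
  stopifnot(inherits(hierarchy, "fibre_hierarchy"))
  formats <- match.arg(formats, c("tiff", "csv", "geojson", "png"),
                       several.ok = TRUE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  dims <- attr(hierarchy, "dims")
  maps <- hierarchy_maps(hierarchy)
  semantic <- semantic_from_hierarchy(hierarchy)
  morpho <- measure_fibres(hierarchy)
  manifest <- list()
  add <- function(file, kind) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(file = file,
                                                         kind = kind)
  }
  fp <- function(suffix) file.path(out_dir, paste0(stem, suffix))

  if ("tiff" %in% formats) {
    write_label_tiff(maps$axon$labels, fp("_axon.tif")); add(fp("_axon.tif"), "axon_mask")
    write_label_tiff(maps$inner_region$labels, fp("_inner.tif")); add(fp("_inner.tif"), "inner_mask")
    write_label_tiff(maps$fibre$labels, fp("_fibre.tif")); add(fp("_fibre.tif"), "fibre_mask")
    write_label_tiff(semantic$labels, fp("_semantic.tif")); add(fp("_semantic.tif"), "semantic_mask")
  }
  if ("csv" %in% formats) {
    out <- dplyr::mutate(morpho, image = stem, .before = 1)
    utils::write.csv(out, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    add(file.path(out_dir, "results.csv"), "results")
  }
  if ("geojson" %in% formats) {
    feats <- list()
    for (kind in names(maps)) {
      sets <- split_label_pixels(maps[[kind]]$labels)
      for (nm in names(sets)) {
        polys <- region_polygons(sets[[nm]], dims)
        for (poly in polys) {
          feats[[length(feats) + 1L]] <- list(
            type = "Feature",
            properties = list(component_kind = kind,
                              label = as.integer(nm),
                              fibre_id = as.integer(nm)),
            geometry = list(
              type = "Polygon",
              coordinates = list(lapply(seq_len(nrow(poly)), function(i) {
                c(poly[i, 1], poly[i, 2])
              }))))
        }
      }
    }
    gj <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(gj, fp("_rois.geojson"), auto_unbox = TRUE,
                         digits = NA)
    add(fp("_rois.geojson"), "rois")
  }
  if ("png" %in% formats) {
    base <- if (!is.null(img)) img$pixels else matrix(0.5, dims[1], dims[2])
    rgb <- array(rep(base, 3), c(dims[1], dims[2], 3))
    cls <- semantic$labels
    # tint: axon green, tongue orange, myelin blue
    tint <- function(ch, cols) {
      v <- rgb[, , ch]
      for (code in 1:3) {
        sel <- cls == code
        v[sel] <- 0.5 * v[sel] + 0.5 * cols[code]
      }
      v
    }
    rgb[, , 1] <- tint(1, c(0.1, 1.0, 0.1))
    rgb[, , 2] <- tint(2, c(0.9, 0.6, 0.2))
    rgb[, , 3] <- tint(3, c(0.1, 0.0, 0.9))
    png::writePNG(rgb, fp("_overlay.png"))
    add(fp("_overlay.png"), "overlay")
  }
  dplyr::bind_rows(manifest)
}

#' Write a probability stack as a 3-channel float TIFF
#'
#' @param prob A [prob_stack()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_prob_tiff <- function(prob, path) {
  tiff::writeTIFF(prob$p, path, bits.per.sample = 32)
  invisible(path)
}

#' @rdname write_prob_tiff
#' @param pixel_size_um Pixel size to attach.
#' @export
read_prob_tiff <- function(path, pixel_size_um = 1) {
  p <- tiff::readTIFF(path)
  prob_stack(p, pixel_size_um, renormalise = TRUE)
}
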