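#' Calibrated 2D grayscale image
#'
#' A minimal container for a single-channel electron-microscopy image:
#' a numeric matrix of intensities (conventionally scaled to `[0, 1]`)
#' plus the physical pixel size.  Rows index image rows (y, increasing
#' downward), columns index x.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @return An object of class `image2d`.
#' @export
image2d <- function(pixels, pixel_size_um) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have at least one row and one column", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um)),
    class = "image2d"
  )
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf(
    "<image2d> %d x %d px, pixel size %.6g um, intensity range [%.4g, %.4g]\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.image2d <- function(x) dim(x$pixels)

#' Read a grayscale TIFF or PNG as a calibrated image
#'
#' Intensities are scaled to `[0, 1]` by dividing by the maximum value of
#' the stored integer type (255 for 8-bit, 65535 for 16-bit), which is the
#' behaviour of the underlying **tiff** and **png** readers.  Multi-channel
#' (RGB/RGBA) input is rejected: the workflow is defined on single-channel
#' TEM data.
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF or PNG file.
#' @param pixel_size_um Physical pixel size in micrometres.
#' @return An [image2d()].
#' @export
load_image <- function(path, pixel_size_um) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)", call. = FALSE)
  )
  if (is.list(px)) {
    stop("multi-page TIFF input is not supported", call. = FALSE)
  }
  if (length(dim(px)) == 3L) {
    # grayscale images are sometimes stored as gray+alpha or replicated RGB
    if (dim(px)[3] >= 3L &&
        isTRUE(all.equal(px[, , 1], px[, , 2])) &&
        isTRUE(all.equal(px[, , 1], px[, , 3]))) {
      px <- px[, , 1]
    } else if (dim(px)[3] == 2L) {
      px <- px[, , 1]
    } else {
      stop("multi-channel (colour) input is not supported; ",
           "supply a single-channel grayscale image", call. = FALSE)
    }
  }
  image2d(px, pixel_size_um)
}

#' Contrast-normalise an image with saturated tails
#'
#' Clips the lowest and highest `saturated_fraction / 2` intensity
#' quantiles and affinely rescales the clipped range to `[0, 1]` (the
#' familiar "enhance contrast with n% saturated pixels" operation).  The
#' saturation budget is split equally between the two tails.
#'
#' @param img An [image2d()].
#' @param saturated_fraction Total fraction of pixels allowed to saturate,
#'   in `[0, 1)`.  Default 0.01 (1%).
#' @return A normalised [image2d()] with intensities in `[0, 1]`.  A
#'   constant input (zero usable range) returns an all-zero image with a
#'   warning so that batch runs can proceed.
#' @export
normalise_image <- function(img, saturated_fraction = 0.01) {
  stopifnot(inherits(img, "image2d"))
  if (!is.numeric(saturated_fraction) || saturated_fraction < 0 ||
      saturated_fraction >= 1) {
    stop("`saturated_fraction` must be in [0, 1)", call. = FALSE)
  }
  v <- img$pixels
  n <- length(v)
  k <- floor(n * saturated_fraction / 2)   # pixels clipped per tail
  s <- sort(as.vector(v))
  lo <- if (k > 0) s[k] else s[1]
  hi <- if (k > 0) s[n - k + 1] else s[n]
  if (hi <= lo) {
    warning("image has zero intensity range after clipping; returning zeros")
    return(image2d(matrix(0, nrow(v), ncol(v)), img$pixel_size_um))
  }
  out <- (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
  image2d(out, img$pixel_size_um)
}

#' Downsample an image by an integer factor (block mean)
#'
#' Each output pixel is the mean of the corresponding `factor` x `factor`
#' block, and the pixel size is multiplied by `factor`.  Block averaging
#' is used (rather than nearest-neighbour decimation) so the operation is
#' anti-aliased and conserves total intensity.  Trailing rows/columns that
#' do not fill a complete block are cropped with a warning.
#'
#' @param img An [image2d()].
#' @param factor Integer downsampling factor, >= 1.
#' @return The downsampled [image2d()].
#' @export
downsample_image <- function(img, factor) {
  stopifnot(inherits(img, "image2d"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) {
    stop("`factor` must be an integer >= 1", call. = FALSE)
  }
  if (factor == 1L) return(img)
  v <- img$pixels
  nr <- nrow(v) %/% factor * factor
  nc <- ncol(v) %/% factor * factor
  if (nr < nrow(v) || nc < ncol(v)) {
    warning(sprintf(
      "image dimensions (%d x %d) not divisible by %d; cropping to %d x %d",
      nrow(v), ncol(v), factor, nr, nc
    ))
    v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  }
  # block mean via two successive one-axis reductions
  rows <- rowsum(v, rep(seq_len(nr %/% factor), each = factor)) / factor
  out <- t(rowsum(t(rows), rep(seq_len(nc %/% factor), each = factor)) / factor)
  image2d(out, img$pixel_size_um * factor)
}
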