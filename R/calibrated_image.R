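#' Calibrated histology image
#'
#' A `calibrated_image` bundles an 8-bit RGB raster with its physical pixel
#' size so that every downstream quantity carries real units. Pixels are
#' stored as an `H x W x 3` numeric array with values in `[0, 255]`;
#' coordinates are 1-based `(row, col)` with the origin at the top-left,
#' matching R's matrix storage. One pixel covers `pixel_size^2` square
#' micrometres.
#'
#' @param pixels Numeric array `H x W x 3` (or `H x W` matrix, replicated to
#'   three channels) with values in `[0, 255]`.
#' @param pixel_size Physical edge length of one pixel in micrometres
#'   (must be `> 0`).
#' @param id Slide identifier string.
#'
#' @return An object of class `calibrated_image` with elements `pixels`,
#'   `pixel_size` and `id`.
#' @export
#' @examples
#' img <- calibrated_image(array(255, c(10, 10, 3)), pixel_size = 1)
#' dim(img$pixels)
calibrated_image <- function(pixels, pixel_size, id = "slide") {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0) {
    stop("calibration error: `pixel_size` must be a single value > 0", call. = FALSE)
  }
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("`pixels` must be an H x W x 3 array or an H x W matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must be finite and in [0, 255]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size), id = as.character(id)),
    class = "calibrated_image"
  )
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<calibrated_image '%s'> %d x %d px @ %.4g um/px (%.3g mm x %.3g mm)\n",
    x$id, d[1], d[2], x$pixel_size,
    d[1] * x$pixel_size / 1000, d[2] * x$pixel_size / 1000
  ))
  invisible(x)
}

#' Read a calibrated image from PNG or TIFF
#'
#' Reads an 8-bit RGB (or grayscale, replicated to RGB) raster and attaches
#' the user-supplied calibration. Calibration is always explicit: scanner
#' metadata embedded in TIFF tags is ignored because it is rarely trustworthy
#' across instruments, and an explicit value is auditable.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams calibrated_image
#' @return A [calibrated_image].
#' @export
load_image <- function(path, pixel_size, id = NULL) {
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop("calibration error: `pixel_size` must be a single value > 0", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raster <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' (need PNG or TIFF)", call. = FALSE)
  )
  if (is.matrix(raster)) raster <- array(rep(raster, 3), c(dim(raster), 3))
  if (dim(raster)[3] > 3) raster <- raster[, , 1:3, drop = FALSE] # drop alpha
  calibrated_image(round(raster * 255), pixel_size,
                   id = id %||% tools::file_path_sans_ext(basename(path)))
}

#' Write a calibrated image to PNG or TIFF
#'
#' @param img A [calibrated_image].
#' @param path Output path; format chosen by extension (`.png`, `.tif(f)`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "calibrated_image"))
  arr <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported image format '", ext, "'", call. = FALSE)
  )
  invisible(path)
}

#' Tissue mask and tissue area
#'
#' Separates tissue from background glass. A pixel is background when it is
#' strictly brighter than `white_cutoff` in all three channels; holes fully
#' enclosed by tissue (the unstained adipocyte lumina) are then filled back
#' in, so lumina count as tissue. The mask's area in square millimetres is
#' the denominator for every per-area quantity (ECM fractions, densities).
#'
#' @param img A [calibrated_image].
#' @param white_cutoff Per-channel luminance above which a pixel is candidate
#'   background (default 240; background glass is near-saturated white).
#' @param min_speck Tissue components smaller than this many pixels are
#'   treated as background speckle (sensor noise dipping a channel below the
#'   cutoff on glass) and removed before hole filling (default 25).
#' @return An object of class `tissue_mask`: list with logical matrix `mask`,
#'   scalar `tissue_area_mm2`, and the originating `pixel_size`.
#' @export
tissue_mask <- function(img, white_cutoff = 240, min_speck = 25) {
  stopifnot(inherits(img, "calibrated_image"))
  px <- img$pixels
  bg <- px[, , 1] > white_cutoff & px[, , 2] > white_cutoff & px[, , 3] > white_cutoff
  tissue <- !bg
  if (any(tissue) && min_speck > 1) {
    comp <- EBImage::bwlabel(tissue)
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    small <- which(sizes < min_speck)
    if (length(small)) tissue[comp %in% small] <- FALSE
  }
  if (any(tissue)) {
    tissue <- EBImage::fillHull(tissue * 1) > 0
  }
  new_tissue_mask(tissue, img$pixel_size)
}

new_tissue_mask <- function(mask, pixel_size) {
  structure(
    list(
      mask = mask,
      tissue_area_mm2 = sum(mask) * pixel_size^2 * 1e-6,
      pixel_size = pixel_size
    ),
    class = "tissue_mask"
  )
}

#' @export
print.tissue_mask <- function(x, ...) {
  cat(sprintf(
    "<tissue_mask> %d x %d px, %.4g mm2 tissue (%.1f%% of frame)\n",
    nrow(x$mask), ncol(x$mask), x$tissue_area_mm2, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask A [tissue_mask] or logical matrix.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  png::writePNG(m * 1, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
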