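#' Color thresholds for elastic-stain classification
#'
#' The elastic (Accustain-type) stain renders elastin fibers black, collagen
#' pink, and leaves adipocyte lumina unstained (near-white). "Black" and
#' "unstained" are luminance/saturation concepts, so classification uses
#' HSL-style luminance `L = (max + min)/2` (0-255 scale) and saturation
#' `S = (max - min) / max` rather than raw RGB distances, which makes it
#' robust to hue drift of the pink and stable for noisy near-white pixels.
#'
#' Within tissue the rules are, in order: `L <= elastin_lum_max` is elastin;
#' `S <= lumen_sat_max` and `L >= lumen_lum_min` is lumen; everything else is
#' collagen. Pixels outside the tissue mask are background.
#'
#' @param elastin_lum_max Luminance ceiling for black elastin fibers
#'   (default 80).
#' @param lumen_lum_min Luminance floor for unstained lumina (default 200).
#' @param lumen_sat_max Saturation ceiling for unstained lumina, in `[0, 1]`
#'   (default 0.15).
#' @return An object of class `color_thresholds`.
#' @export
color_thresholds <- function(elastin_lum_max = 80, lumen_lum_min = 200,
                             lumen_sat_max = 0.15) {
  if (!(elastin_lum_max >= 0 && elastin_lum_max < lumen_lum_min &&
        lumen_lum_min <= 255)) {
    stop("need 0 <= elastin_lum_max < lumen_lum_min <= 255", call. = FALSE)
  }
  if (lumen_sat_max < 0 || lumen_sat_max > 1) {
    stop("`lumen_sat_max` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(elastin_lum_max = elastin_lum_max, lumen_lum_min = lumen_lum_min,
         lumen_sat_max = lumen_sat_max),
    class = "color_thresholds"
  )
}

# Luminance (0-255) and saturation (0-1) from an RGB array. Luminance is the
# HSL lightness (max+min)/2; saturation is the chroma relative to the maximum
# channel, which stays small for noisy near-white pixels (the HSL saturation
# denominator vanishes near white and would amplify sensor noise).
rgb_lum_sat <- function(px) {
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  lum <- (mx + mn) / 2
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  list(lum = lum, sat = sat)
}

#' Classify pixels of an elastic-stained section
#'
#' Assigns each pixel exactly one label: `0` background, `1` lumen
#' (unstained adipocyte interior), `2` collagen (pink septa), `3` elastin
#' (black fibers). See [color_thresholds()] for the decision rules.
#'
#' @param img A [calibrated_image].
#' @param mask A [tissue_mask] with the same dimensions.
#' @param thr A [color_thresholds] object.
#' @return An object of class `stain_map`: integer label matrix `labels`,
#'   the `thresholds` used, and `pixel_size`.
#' @export
classify_pixels <- function(img, mask, thr = color_thresholds()) {
  stopifnot(inherits(img, "calibrated_image"), inherits(mask, "tissue_mask"),
            inherits(thr, "color_thresholds"))
  d <- dim(img$pixels)
  if (!all(d[1:2] == dim(mask$mask))) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  ls <- rgb_lum_sat(img$pixels)
  lab <- matrix(STAIN_COLLAGEN, d[1], d[2])
  lab[ls$lum <= thr$elastin_lum_max] <- STAIN_ELASTIN
  lab[ls$sat <= thr$lumen_sat_max & ls$lum >= thr$lumen_lum_min] <- STAIN_LUMEN
  lab[!mask$mask] <- STAIN_BACKGROUND
  structure(
    list(labels = lab, thresholds = thr, pixel_size = img$pixel_size),
    class = "stain_map"
  )
}

STAIN_BACKGROUND <- 0L
STAIN_LUMEN <- 1L
STAIN_COLLAGEN <- 2L
STAIN_ELASTIN <- 3L

stain_level_names <- c(background = 0L, lumen = 1L, collagen = 2L, elastin = 3L)

#' @export
print.stain_map <- function(x, ...) {
  n <- length(x$labels)
  counts <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf(
    "<stain_map> %d x %d px | background %.1f%%, lumen %.1f%%, collagen %.1f%%, elastin %.1f%%\n",
    nrow(x$labels), ncol(x$labels),
    100 * counts[1] / n, 100 * counts[2] / n, 100 * counts[3] / n, 100 * counts[4] / n
  ))
  invisible(x)
}

#' ECM and lumen area fractions
#'
#' Percent of tissue area occupied by collagen, elastin and lumen. The three
#' fractions sum to 100 exactly (before any rounding) because every tissue
#' pixel carries exactly one of the three labels.
#'
#' @param stain A [stain_map] derived from `mask`.
#' @param mask The [tissue_mask] it was derived from.
#' @param slide_id Identifier carried into the output row.
#' @return A one-row tibble: `slide_id`, `pct_collagen`, `pct_elastin`,
#'   `pct_lumen`, `tissue_area_mm2`.
#' @export
ecm_fractions <- function(stain, mask, slide_id = "slide") {
  stopifnot(inherits(stain, "stain_map"), inherits(mask, "tissue_mask"))
  if (!all(dim(stain$labels) == dim(mask$mask))) {
    stop("stain map and mask dimensions differ", call. = FALSE)
  }
  n_tissue <- sum(mask$mask)
  if (n_tissue == 0) {
    stop("undefined fraction: tissue mask contains no tissue pixels", call. = FALSE)
  }
  lab <- stain$labels[mask$mask]
  tibble::tibble(
    slide_id = slide_id,
    pct_collagen = 100 * sum(lab == STAIN_COLLAGEN) / n_tissue,
    pct_elastin = 100 * sum(lab == STAIN_ELASTIN) / n_tissue,
    pct_lumen = 100 * sum(lab == STAIN_LUMEN) / n_tissue,
    tissue_area_mm2 = mask$tissue_area_mm2
  )
}

#' Write a stain map as an indexed-palette PNG
#'
#' Palette: lumen white, collagen magenta, elastin black, background gray.
#'
#' @param stain A [stain_map].
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_stain_map <- function(stain, path) {
  pal <- rbind(
    background = c(128, 128, 128),
    lumen = c(255, 255, 255),
    collagen = c(255, 0, 255),
    elastin = c(0, 0, 0)
  ) / 255
  lab <- stain$labels
  arr <- array(0, c(dim(lab), 3))
  for (k in 1:3) arr[, , k] <- matrix(pal[lab + 1L, k], nrow(lab), ncol(lab))
  png::writePNG(arr, path)
  invisible(path)
}
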