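#' Segmentation run configuration
#'
#' Bundles every tunable of the pipeline with its default. A config written
#' with [write_config()] and re-read with [read_config()] reproduces the
#' identical run.
#'
#' @param pixel_size Micrometres per pixel edge of the input images.
#' @param white_cutoff Background luminance cutoff (see [tissue_mask()]).
#' @param thresholds A [color_thresholds] object.
#' @param gvf List with `mu`, `n_iter`, `sigma` (edge-map smoothing) for
#'   [edge_map()] / [compute_gvf()].
#' @param snake A [snake_params] object.
#' @param min_separation Seed separation, um (see [detect_seeds()]).
#' @param init_radius_factor Snake initial radius as a fraction of the
#'   seed's distance-transform value (floor 3 px).
#' @param filters Numeric `(min_area, max_area)` inclusion bounds, um2.
#' @param trim_to_lumen Restrict each resolved cell region to its
#'   lumen-classified pixels before measuring (default `TRUE`). The contour
#'   assigns territory; the cross-sectional area of an adipocyte is the
#'   unstained profile inside it, so stained ECM pixels swept up by a
#'   bulging contour are returned to the ECM.
#' @param histogram List with `bin_width` and `range` for
#'   [build_histogram()].
#' @return An object of class `segment_config`.
#' @export
segment_config <- function(pixel_size = 1.0, white_cutoff = 240,
                           thresholds = color_thresholds(),
                           gvf = list(mu = 0.2, n_iter = 2000, sigma = 1.5),
                           snake = snake_params(),
                           min_separation = 25, init_radius_factor = 0.7,
                           filters = c(500, 10000), trim_to_lumen = TRUE,
                           histogram = list(bin_width = 500, range = c(500, 10000))) {
  cfg <- structure(
    list(pixel_size = pixel_size, white_cutoff = white_cutoff,
         thresholds = thresholds, gvf = gvf, snake = snake,
         min_separation = min_separation,
         init_radius_factor = init_radius_factor,
         filters = filters, trim_to_lumen = trim_to_lumen,
         histogram = histogram),
    class = "segment_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$pixel_size <= 0) stop("invalid config field `pixel_size`: must be > 0", call. = FALSE)
  if (cfg$filters[1] >= cfg$filters[2]) {
    stop("invalid config field `filters`: min_area must be < max_area", call. = FALSE)
  }
  if (cfg$gvf$mu < 0 || cfg$gvf$n_iter < 0) {
    stop("invalid config field `gvf`: mu and n_iter must be >= 0", call. = FALSE)
  }
  if (cfg$min_separation <= 0) {
    stop("invalid config field `min_separation`: must be > 0", call. = FALSE)
  }
  if (cfg$histogram$bin_width <= 0 ||
      cfg$histogram$range[1] >= cfg$histogram$range[2]) {
    stop("invalid config field `histogram`", call. = FALSE)
  }
  invisible(cfg)
}

#' Write / read a run configuration (YAML)
#'
#' @param cfg A [segment_config].
#' @param path YAML file path.
#' @return `path` (write) or a `segment_config` (read).
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- list(
    pixel_size = cfg$pixel_size, white_cutoff = cfg$white_cutoff,
    thresholds = unclass(cfg$thresholds), gvf = cfg$gvf,
    snake = unclass(cfg$snake), min_separation = cfg$min_separation,
    init_radius_factor = cfg$init_radius_factor,
    filters = as.numeric(cfg$filters),
    trim_to_lumen = cfg$trim_to_lumen, histogram = cfg$histogram
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  segment_config(
    pixel_size = raw$pixel_size, white_cutoff = raw$white_cutoff,
    thresholds = do.call(color_thresholds, raw$thresholds),
    gvf = raw$gvf,
    snake = do.call(snake_params, raw$snake),
    min_separation = raw$min_separation,
    init_radius_factor = raw$init_radius_factor,
    filters = as.numeric(raw$filters),
    trim_to_lumen = raw$trim_to_lumen,
    histogram = list(bin_width = raw$histogram$bin_width,
                     range = as.numeric(raw$histogram$range))
  )
}

#' Segment every adipocyte on a slide
#'
#' End-to-end pipeline: tissue mask, stain classification, seed detection
#' (or user-supplied seeds), color-gradient edge map, GVF field, one snake
#' per seed (initial radius `max(3, init_radius_factor x distance-transform
#' value)`), overlap resolution into an exclusive label raster, and
#' calibrated per-cell measurement. Deterministic: identical image and
#' config give identical output.
#'
#' @param img A [calibrated_image].
#' @param config A [segment_config]; its `pixel_size` is ignored in favor of
#'   the image's own calibration.
#' @param seeds Optional `seed_set` overriding automatic detection (e.g.
#'   hand-corrected via [read_seeds()]).
#' @return An object of class `slide_segmentation`: `mask`, `stain`,
#'   `seeds`, `contours`, `labels`, `cells` (tibble), `ecm` (tibble),
#'   `config`.
#' @export
segment_slide <- function(img, config = segment_config(), seeds = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  validate_config(config)
  mask <- tissue_mask(img, white_cutoff = config$white_cutoff)
  stain <- classify_pixels(img, mask, config$thresholds)
  if (is.null(seeds)) {
    seeds <- detect_seeds(stain, min_separation = config$min_separation)
  }
  f <- edge_map(img, stain, sigma = config$gvf$sigma)
  field <- compute_gvf(f, mu = config$gvf$mu, n_iter = config$gvf$n_iter)
  field_norm <- normalize_field(field)
  contours <- purrr::pmap(
    list(seeds$row, seeds$col, seeds$dist_px),
    function(r, c, d) {
      init_r <- max(3, config$init_radius_factor * (if (is.na(d)) 3 else d))
      evolve_contour(c(r, c), field, config$snake, init_radius = init_r,
                     approach_field = field_norm)
    }
  )
  labels <- resolve_overlaps(contours, dim(f))
  if (isTRUE(config$trim_to_lumen)) {
    labels[stain$labels != STAIN_LUMEN] <- 0L
  }
  cells <- measure_cells(labels, img$pixel_size,
                         min_area = config$filters[1],
                         max_area = config$filters[2],
                         contours = contours, slide_id = img$id)
  ecm <- if (mask$tissue_area_mm2 > 0) {
    ecm_fractions(stain, mask, slide_id = img$id)
  } else NULL
  structure(
    list(mask = mask, stain = stain, seeds = seeds, contours = contours,
         labels = labels, cells = cells, ecm = ecm, config = config),
    class = "slide_segmentation"
  )
}

#' @export
print.slide_segmentation <- function(x, ...) {
  cat(sprintf(
    "<slide_segmentation '%s'> %d seeds, %d cells (%d included), %.3g mm2 tissue\n",
    x$cells$slide_id[1] %||% "slide", nrow(x$seeds), nrow(x$cells),
    sum(x$cells$included), x$mask$tissue_area_mm2
  ))
  invisible(x)
}

#' Summarize a segmentation into one slide-summary row
#'
#' @param seg A `slide_segmentation` from [segment_slide()].
#' @return A one-row `slide_summary` tibble (see [slide_summary()]).
#' @export
summarize_segmentation <- function(seg) {
  stopifnot(inherits(seg, "slide_segmentation"))
  slide_summary(seg$cells, ecm = seg$ecm,
                bin_width = seg$config$histogram$bin_width,
                range = seg$config$histogram$range)
}

#' Paired pre/post comparison across subjects
#'
#' Joins per-subject pre and post slide summaries and runs a paired t-test
#' on each shared metric: mean CSA, ECM fractions, and any `density_`
#' column present in both tables.
#'
#' @param pre,post Data frames with a `subject_id` column and metric
#'   columns; one row per subject (e.g. stacked [summarize_segmentation()]
#'   rows with `subject_id` added).
#' @return A tibble with one row per metric: `metric`, `n_pairs`,
#'   `mean_pre`, `mean_post`, `mean_difference`, `pct_change`,
#'   `t_statistic`, `df`, `p_value`.
#' @export
compare_cohorts <- function(pre, post) {
  pre <- tibble::as_tibble(pre); post <- tibble::as_tibble(post)
  if (!"subject_id" %in% names(pre) || !"subject_id" %in% names(post)) {
    stop("both tables need a `subject_id` column", call. = FALSE)
  }
  missing_post <- setdiff(pre$subject_id, post$subject_id)
  missing_pre <- setdiff(post$subject_id, pre$subject_id)
  if (length(missing_post) || length(missing_pre)) {
    stop("unmatched subjects: ",
         paste(c(missing_post, missing_pre), collapse = ", "), call. = FALSE)
  }
  candidates <- c("mean_csa_um2", "pct_collagen", "pct_elastin")
  candidates <- c(candidates, grep("^density_", names(pre), value = TRUE))
  metrics <- intersect(intersect(candidates, names(pre)), names(post))
  if (length(metrics) == 0) stop("no shared metric columns found", call. = FALSE)
  ord <- match(pre$subject_id, post$subject_id)
  purrr::map_dfr(metrics, function(m) {
    pt <- paired_t(pre[[m]], post[[m]][ord])
    tibble::tibble(
      metric = m, n_pairs = pt$n_pairs,
      mean_pre = pt$mean_pre, mean_post = pt$mean_post,
      mean_difference = pt$mean_difference,
      pct_change = 100 * pt$mean_difference / pt$mean_pre,
      t_statistic = pt$t_statistic, df = pt$df, p_value = pt$p_value
    )
  })
}
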