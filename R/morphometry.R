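#' Measure calibrated per-cell areas from a label raster
#'
#' Converts each labeled region into a cell record with its cross-sectional
#' area in square micrometres (`area_um2 = pixel count x pixel_size^2`).
#' A cell is `included` when its contour converged and its area lies within
#' `[min_area, max_area]`. The default filter `[500, 10000]` um2 takes its
#' floor from the smallest adipocytes the method is designed to measure and
#' pads the ceiling above the largest commonly reported profile so true
#' large cells are not truncated.
#'
#' @param labels Integer label matrix from [resolve_overlaps()].
#' @param pixel_size Micrometres per pixel edge (`> 0`).
#' @param min_area,max_area Inclusion bounds in um2 (`min_area < max_area`).
#' @param contours Optional list of `cell_contour` objects indexed by label
#'   id, supplying seeds and convergence flags; absent cells default to
#'   `converged = TRUE` and seed `NA`.
#' @param slide_id Identifier carried into the output.
#' @return A tibble: `slide_id`, `cell_id`, `row`, `col` (seed), `area_px`,
#'   `area_um2`, `converged`, `included`.
#' @export
measure_cells <- function(labels, pixel_size, min_area = 500, max_area = 10000,
                          contours = NULL, slide_id = "slide") {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    stop("calibration error: `pixel_size` must be > 0", call. = FALSE)
  }
  if (min_area >= max_area) stop("`min_area` must be < `max_area`", call. = FALSE)
  ids <- sort(unique(labels[labels > 0]))
  counts <- tabulate(labels[labels > 0], nbins = max(labels, 0L))
  seed_r <- rep(NA_real_, length(ids)); seed_c <- seed_r
  conv <- rep(TRUE, length(ids))
  if (!is.null(contours)) {
    for (k in seq_along(ids)) {
      ct <- contours[[ids[k]]]
      seed_r[k] <- ct$seed[1]; seed_c[k] <- ct$seed[2]
      conv[k] <- ct$converged
    }
  }
  area_um2 <- counts[ids] * pixel_size^2
  tibble::tibble(
    slide_id = slide_id,
    cell_id = as.integer(ids),
    row = seed_r, col = seed_c,
    area_px = as.integer(counts[ids]),
    area_um2 = area_um2,
    converged = conv,
    included = conv & area_um2 >= min_area & area_um2 <= max_area
  )
}

#' Relative-frequency histogram of cell cross-sectional area
#'
#' Bins the included cells into half-open bins `[lo, lo + width)` spanning
#' `range`; cells outside `range` are dropped before normalization, and
#' relative frequencies sum to 1 over the reported bins.
#'
#' @param cells Cell tibble from [measure_cells()] (or any data frame with
#'   `area_um2` and optionally `included`).
#' @param bin_width Bin width in um2 (default 500).
#' @param range Numeric `(lo, hi)` in um2 (default `c(500, 10000)`).
#' @return A tibble: `bin_lo`, `bin_hi`, `n`, `freq`.
#' @export
build_histogram <- function(cells, bin_width = 500, range = c(500, 10000)) {
  a <- cells$area_um2
  if (!is.null(cells$included)) a <- a[cells$included]
  a <- a[a >= range[1] & a < range[2]]
  if (length(a) == 0) stop("no included cells to bin", call. = FALSE)
  breaks <- seq(range[1], range[2], by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  bin <- findInterval(a, breaks, rightmost.closed = FALSE)
  n <- tabulate(bin, nbins = length(breaks) - 1)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    n = as.integer(n),
    freq = n / sum(n)
  )
}

#' Per-slide summary
#'
#' One row per slide: number of included cells, their mean cross-sectional
#' area, ECM fractions if supplied, and the relative-frequency histogram as
#' a list-column.
#'
#' @param cells Cell tibble from [measure_cells()].
#' @param ecm Optional one-row tibble from [ecm_fractions()].
#' @param slide_id Identifier; defaults to the one carried in `cells`.
#' @param bin_width,range Histogram parameters (see [build_histogram()]).
#' @return A one-row tibble of class `slide_summary`.
#' @export
slide_summary <- function(cells, ecm = NULL, slide_id = NULL,
                          bin_width = 500, range = c(500, 10000)) {
  slide_id <- slide_id %||% cells$slide_id[1] %||% "slide"
  inc <- cells[cells$included, , drop = FALSE]
  out <- tibble::tibble(
    slide_id = slide_id,
    n_cells_included = nrow(inc),
    mean_csa_um2 = if (nrow(inc)) mean(inc$area_um2) else NA_real_,
    histogram = list(
      if (nrow(inc)) build_histogram(inc, bin_width, range) else NULL
    )
  )
  if (!is.null(ecm)) {
    out$pct_collagen <- ecm$pct_collagen
    out$pct_elastin <- ecm$pct_elastin
    out$pct_lumen <- ecm$pct_lumen
    out$tissue_area_mm2 <- ecm$tissue_area_mm2
  }
  class(out) <- c("slide_summary", class(out))
  out
}

#' Paired pre/post comparison (paired t-test)
#'
#' Classical paired t on the per-subject differences `post - pre`, two-sided.
#' If all differences are identical: zero differences give `t = 0, p = 1`
#' (nothing changed); a non-zero constant difference has zero variance and
#' raises a degenerate-variance error.
#'
#' @param pre,post Numeric vectors of per-subject values, paired by position,
#'   equal length `n >= 2`.
#' @return An object of class `paired_comparison` with fields `n_pairs`,
#'   `mean_pre`, `mean_post`, `mean_difference`, `t_statistic`, `df`,
#'   `p_value`. Use [tidy()] / [glance()] for tibble output.
#' @export
paired_t <- function(pre, post) {
  if (length(pre) != length(post)) stop("`pre` and `post` lengths differ", call. = FALSE)
  n <- length(pre)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- post - pre
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      res <- list(n_pairs = n, mean_pre = mean(pre), mean_post = mean(post),
                  mean_difference = 0, t_statistic = 0, df = n - 1, p_value = 1)
      class(res) <- "paired_comparison"
      return(res)
    }
    stop("degenerate variance: all differences identical and non-zero", call. = FALSE)
  }
  tt <- t.test(post, pre, paired = TRUE)
  res <- list(
    n_pairs = n, mean_pre = mean(pre), mean_post = mean(post),
    mean_difference = mean(d),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
  class(res) <- "paired_comparison"
  res
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired comparison (n = %d): %.4g -> %.4g (diff %.4g), t(%d) = %.3f, p = %.4g\n",
    x$n_pairs, x$mean_pre, x$mean_post, x$mean_difference, x$df,
    x$t_statistic, x$p_value
  ))
  invisible(x)
}

#' Validate automated against manual per-slide means
#'
#' Pearson correlation (two-sided) between paired per-slide mean
#' cross-sectional areas measured automatically and manually.
#'
#' @param auto,manual Numeric vectors of per-slide mean CSA, equal length
#'   `n >= 3`, each with non-zero variance.
#' @return An object of class `validation_report` with `n`, `r`, `p_value`.
#' @export
validate_against_manual <- function(auto, manual) {
  if (length(auto) != length(manual)) stop("vector lengths differ", call. = FALSE)
  if (length(auto) < 3) stop("need at least 3 slides", call. = FALSE)
  if (sd(auto) == 0 || sd(manual) == 0) {
    stop("zero variance in one of the inputs", call. = FALSE)
  }
  ct <- cor.test(auto, manual, method = "pearson")
  res <- list(n = length(auto), r = unname(ct$estimate), p_value = ct$p.value)
  class(res) <- "validation_report"
  res
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Manual-vs-automated validation: n = %d, r = %.3f, p = %.4g\n",
              x$n, x$r, x$p_value))
  invisible(x)
}
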