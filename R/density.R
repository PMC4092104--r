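#' Normalize counted objects to events per square millimetre
#'
#' Counts (mast cells, macrophages by polarity class, capillaries, vessels,
#' or any user category) are divided by the tissue area of the slide. Counts
#' may be given either as point annotations (`row`, `col`, one row per
#' event) or as pre-tallied integers (`count` column). Annotated points
#' falling outside the tissue mask are dropped with a warning before
#' counting. Clustered events must be annotated as individual points, one
#' per cell.
#'
#' @param counts A data frame with `slide_id`, `category`, and either
#'   point columns `row`/`col` or a `count` column.
#' @param mask A [tissue_mask] with `tissue_area_mm2 > 0`.
#' @param slide_id Identifier used when `counts` lacks a `slide_id` column.
#' @return A tibble: `slide_id`, `category`, `count`, `tissue_area_mm2`,
#'   `density_per_mm2`, one row per category.
#' @export
to_density <- function(counts, mask, slide_id = "slide") {
  stopifnot(inherits(mask, "tissue_mask"))
  if (mask$tissue_area_mm2 <= 0) {
    stop("zero tissue area: density undefined", call. = FALSE)
  }
  counts <- tibble::as_tibble(counts)
  if (!"slide_id" %in% names(counts)) counts$slide_id <- slide_id
  if (all(c("row", "col") %in% names(counts)) && !"count" %in% names(counts)) {
    inside <- mask$mask[cbind(round(counts$row), round(counts$col))]
    if (any(!inside)) {
      warning(sum(!inside), " annotated point(s) outside tissue dropped",
              call. = FALSE)
      counts <- counts[inside, , drop = FALSE]
    }
    tallied <- dplyr::count(counts, .data$slide_id, .data$category, name = "count")
  } else if ("count" %in% names(counts)) {
    if (any(counts$count < 0)) stop("counts must be >= 0", call. = FALSE)
    tallied <- dplyr::summarise(
      dplyr::group_by(counts, .data$slide_id, .data$category),
      count = sum(.data$count), .groups = "drop"
    )
  } else {
    stop("`counts` needs either `row`/`col` point columns or a `count` column",
         call. = FALSE)
  }
  dplyr::mutate(
    tallied,
    tissue_area_mm2 = mask$tissue_area_mm2,
    density_per_mm2 = .data$count / mask$tissue_area_mm2
  )
}

#' Macrophage polarity fractions
#'
#' Fractions of M1, M2 and mixed-phenotype macrophages out of their total,
#' per slide. All three categories must be present (zero counts allowed,
#' but not an all-zero total).
#'
#' @param counts A data frame with `slide_id` (optional), `category` in
#'   `{macrophage_M1, macrophage_M2, macrophage_mixed}` (or bare
#'   `M1`/`M2`/`mixed`), and `count`.
#' @return A tibble: `slide_id`, `total`, `frac_M1`, `frac_M2`, `frac_mixed`.
#' @export
polarity_fractions <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"slide_id" %in% names(counts)) counts$slide_id <- "slide"
  norm <- sub("^macrophage_", "", counts$category)
  counts$category <- norm
  out <- lapply(split(counts, counts$slide_id), function(df) {
    if (!all(c("M1", "M2", "mixed") %in% df$category)) {
      stop("slide '", df$slide_id[1],
           "': all of M1, M2 and mixed categories are required", call. = FALSE)
    }
    g <- vapply(c("M1", "M2", "mixed"),
                function(k) sum(df$count[df$category == k]), numeric(1))
    total <- sum(g)
    if (total == 0) {
      stop("slide '", df$slide_id[1], "': all-zero macrophage counts", call. = FALSE)
    }
    tibble::tibble(slide_id = df$slide_id[1], total = total,
                   frac_M1 = g[["M1"]] / total, frac_M2 = g[["M2"]] / total,
                   frac_mixed = g[["mixed"]] / total)
  })
  dplyr::bind_rows(out)
}

#' Read / write count and density tables
#'
#' Point files have columns `slide_id, category, row, col` (one point per
#' line); tally files have `slide_id, category, count`.
#'
#' @param path CSV path.
#' @return A tibble (read) or `path` invisibly (write).
#' @export
read_counts <- function(path) tibble::as_tibble(read.csv(path))

#' @rdname read_counts
#' @param densities Density tibble from [to_density()].
#' @export
write_densities <- function(densities, path) {
  write.csv(as.data.frame(densities), path, row.names = FALSE)
  invisible(path)
}
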