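#' Match detected seeds to ground-truth cells
#'
#' A seed is a candidate match for the truth cell whose lumen region it
#' falls in; when several seeds land in one cell, the one nearest the cell's
#' centroid wins and the rest are spurious. Precision is matched seeds over
#' all seeds; recall is matched cells over all truth cells.
#'
#' @param seeds A `seed_set` from [detect_seeds()].
#' @param slide A `synthetic_slide` (or any list with `truth_labels` and
#'   `truth_cells`).
#' @return A list: `pairs` (tibble `seed_id`, `cell_id`, `dist_to_centroid`),
#'   `n_matched`, `precision`, `recall`.
#' @export
match_seeds <- function(seeds, slide) {
  tl <- slide$truth_labels
  tc <- slide$truth_cells
  if (nrow(seeds) == 0) {
    return(list(pairs = tibble::tibble(seed_id = integer(), cell_id = integer(),
                                       dist_to_centroid = numeric()),
                n_matched = 0L, precision = NA_real_, recall = 0))
  }
  hit <- tl[cbind(seeds$row, seeds$col)]
  cand <- tibble::tibble(seed_id = seeds$seed_id, cell_id = hit,
                         row = seeds$row, col = seeds$col)
  cand <- cand[cand$cell_id > 0L, , drop = FALSE]
  cand <- dplyr::left_join(cand, tc[, c("cell_id", "row", "col")],
                           by = "cell_id", suffix = c("", "_truth"))
  cand$dist_to_centroid <- sqrt((cand$row - cand$row_truth)^2 +
                                  (cand$col - cand$col_truth)^2)
  cand <- cand[order(cand$dist_to_centroid), , drop = FALSE]
  pairs <- cand[!duplicated(cand$cell_id), c("seed_id", "cell_id", "dist_to_centroid")]
  list(
    pairs = tibble::as_tibble(pairs),
    n_matched = nrow(pairs),
    precision = nrow(pairs) / nrow(seeds),
    recall = nrow(pairs) / nrow(tc)
  )
}

#' Per-cell segmentation accuracy against ground truth
#'
#' Pairs each segmented cell with the truth cell containing its seed and
#' reports the relative area error and intersection-over-union of the two
#' regions.
#'
#' @param labels Segmented label raster from [resolve_overlaps()].
#' @param cells Cell tibble from [measure_cells()] (supplies seeds).
#' @param slide The `synthetic_slide` the segmentation ran on.
#' @return A tibble: `cell_id`, `truth_id`, `area_um2`, `truth_area_um2`,
#'   `rel_error` (signed, fraction of truth), `iou`.
#' @export
segmentation_metrics <- function(labels, cells, slide) {
  tl <- slide$truth_labels
  ps <- slide$recipe$pixel_size
  auto_idx <- split(which(labels > 0L), labels[labels > 0L])
  truth_idx <- split(which(tl > 0L), tl[tl > 0L])
  rows <- purrr::pmap_dfr(
    list(cells$cell_id, cells$row, cells$col, cells$area_um2),
    function(cid, sr, sc, a_um2) {
      if (is.na(sr)) return(NULL)
      tid <- tl[round(sr), round(sc)]
      if (tid == 0L) return(NULL)
      ai <- auto_idx[[as.character(cid)]]
      ti <- truth_idx[[as.character(tid)]]
      if (is.null(ai) || is.null(ti)) return(NULL)
      inter <- length(intersect(ai, ti))
      tibble::tibble(
        cell_id = cid, truth_id = as.integer(tid),
        area_um2 = a_um2, truth_area_um2 = length(ti) * ps^2,
        rel_error = (length(ai) - length(ti)) / length(ti),
        iou = inter / (length(ai) + length(ti) - inter)
      )
    }
  )
  # if two segmented cells point at one truth cell keep the better overlap
  rows <- rows[order(-rows$iou), , drop = FALSE]
  rows <- rows[!duplicated(rows$truth_id), , drop = FALSE]
  rows[order(rows$cell_id), , drop = FALSE]
}
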