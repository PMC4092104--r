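#' Plot the CSA histogram of a slide summary
#'
#' @param object A one-row `slide_summary` tibble.
#' @param ... Unused.
#' @return A ggplot: relative frequency of cell cross-sectional area.
#' @export
autoplot.slide_summary <- function(object, ...) {
  h <- object$histogram[[1]]
  if (is.null(h)) stop("slide summary has no histogram (no included cells)", call. = FALSE)
  h$mid <- (h$bin_lo + h$bin_hi) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$freq)) +
    ggplot2::geom_col(width = (h$bin_hi - h$bin_lo)[1] * 0.92,
                      fill = "grey35") +
    ggplot2::labs(
      x = expression("Cross-sectional area (" * mu * m^2 * ")"),
      y = "Relative frequency",
      title = object$slide_id[1]
    ) +
    ggplot2::theme_minimal()
}

#' Plot a stain classification map
#'
#' Lumen white, collagen magenta, elastin black, background gray.
#'
#' @param object A `stain_map` from [classify_pixels()].
#' @param max_px Downsampling cap on the longer image side (default 512) to
#'   keep the plot light.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.stain_map <- function(object, max_px = 512, ...) {
  lab <- object$labels
  step <- max(1L, ceiling(max(dim(lab)) / max_px))
  lab <- lab[seq(1, nrow(lab), by = step), seq(1, ncol(lab), by = step)]
  df <- tidyr::expand_grid(row = seq_len(nrow(lab)), col = seq_len(ncol(lab)))
  df$class <- factor(
    c("background", "lumen", "collagen", "elastin")[as.vector(lab) + 1L],
    levels = c("background", "lumen", "collagen", "elastin")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      background = "grey60", lumen = "white",
      collagen = "magenta3", elastin = "black"
    ), drop = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Stain class") +
    ggplot2::theme_void()
}

#' Overlay segmented contours on the slide image
#'
#' @param seg A `slide_segmentation` from [segment_slide()].
#' @param max_cells Cap on the number of contours drawn (default all).
#' @return A ggplot with cell outlines and seeds over a grayscale rendering.
#' @export
plot_segmentation <- function(seg, max_cells = Inf) {
  stopifnot(inherits(seg, "slide_segmentation"))
  ids <- utils::head(seq_along(seg$contours), max_cells)
  poly <- purrr::map_dfr(ids, function(i) {
    V <- seg$contours[[i]]$vertices
    tibble::tibble(cell_id = i, row = c(V[, 1], V[1, 1]),
                   col = c(V[, 2], V[1, 2]))
  })
  ggplot2::ggplot() +
    ggplot2::geom_path(
      data = poly,
      ggplot2::aes(x = .data$col, y = .data$row, group = .data$cell_id),
      color = "red3", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = seg$seeds,
      ggplot2::aes(x = .data$col, y = .data$row),
      size = 0.5, color = "blue3"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
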