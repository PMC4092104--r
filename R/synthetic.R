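#' Recipe for a synthetic elastic-stained slide
#'
#' Describes one simulated slide: canvas, calibration, number of adipocytes,
#' the target cell-size range from which per-cell area targets are drawn,
#' septum geometry, elastin load, and noise. Defaults emulate a typical
#' field of elastic-stained human subcutaneous adipose at 1 um/px: tightly
#' packed near-white polygonal lumina spanning roughly 500-8700 um2,
#' separated by ~6 um pink collagen septa carrying sparse black elastin
#' fibers, with a gentle illumination gradient and additive sensor noise.
#'
#' @param width_px,height_px Canvas size in pixels.
#' @param pixel_size Micrometres per pixel edge.
#' @param n_cells Number of adipocytes to place (`>= 1`).
#' @param area_range Target cell area range `(lo, hi)` in um2; per-cell
#'   targets are drawn uniformly from it. Realized (ground-truth) areas come
#'   from the rendered tessellation and are recorded exactly.
#' @param septum_width Collagen septum width between lumina, um.
#' @param elastin_fraction Target elastin load as percent of tissue area.
#' @param noise_sd Additive Gaussian channel noise SD (8-bit counts);
#'   clipped to `[0, 255]`.
#' @param tissue_coverage Fraction of the canvas covered by tissue; `1`
#'   fills the frame, smaller values place an elliptical tissue region on a
#'   white glass background.
#' @param illumination_amp Amplitude of a linear multiplicative illumination
#'   gradient across the frame (0.02 = +/-2 percent).
#' @param rng_seed Integer seed; regeneration with the same recipe and seed
#'   is bit-identical.
#' @return An object of class `slide_recipe`.
#' @export
slide_recipe <- function(width_px = 1024, height_px = 1024, pixel_size = 1.0,
                         n_cells = 200, area_range = c(500, 8700),
                         septum_width = 6, elastin_fraction = 3,
                         noise_sd = 6, tissue_coverage = 1,
                         illumination_amp = 0.02, rng_seed = 1) {
  stopifnot(
    width_px >= 32, height_px >= 32, pixel_size > 0, n_cells >= 1,
    length(area_range) == 2, area_range[1] > 0, area_range[1] < area_range[2],
    septum_width >= 0, elastin_fraction >= 0, noise_sd >= 0,
    tissue_coverage > 0, tissue_coverage <= 1, rng_seed == floor(rng_seed)
  )
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         pixel_size = pixel_size, n_cells = as.integer(n_cells),
         area_range = area_range, septum_width = septum_width,
         elastin_fraction = elastin_fraction, noise_sd = noise_sd,
         tissue_coverage = tissue_coverage,
         illumination_amp = illumination_amp,
         rng_seed = as.integer(rng_seed)),
    class = "slide_recipe"
  )
}

# Reference stain colors of the renderer (8-bit RGB).
SYNTH_COLORS <- list(
  lumen = c(246, 246, 246),
  collagen = c(231, 146, 180),
  elastin = c(38, 32, 36),
  background = c(255, 255, 255)
)

#' Generate a synthetic elastic-stained slide with exact ground truth
#'
#' Construction: per-cell area targets are drawn uniformly from
#' `area_range`; cell centers are placed by dart throwing with a
#' radius-dependent minimum separation (largest first); the canvas is
#' tessellated by the power diagram of the placed centers (weights from the
#' target radii, so realized sizes track targets); each region is shrunk by
#' half the septum width to form the pink collagen septa; black elastin
#' fibers are planted as random curvilinear strokes inside the septa until
#' the target elastin fraction of tissue is met; finally an illumination
#' gradient and clipped Gaussian channel noise are applied. Every
#' ground-truth raster and table is recorded before noise.
#'
#' @param recipe A [slide_recipe].
#' @param id Slide identifier.
#' @return An object of class `synthetic_slide`: `image`
#'   ([calibrated_image]), `tissue` (logical matrix), `truth_labels`
#'   (integer matrix of lumen regions), `truth_cells` (tibble: `cell_id`,
#'   `row`, `col` centroid, `area_px`, `area_um2`, `edge`), `truth_stain`
#'   ([classify_pixels()]-style `stain_map`), and the `recipe`.
#' @export
generate_slide <- function(recipe, id = "synthetic") {
  stopifnot(inherits(recipe, "slide_recipe"))
  withr::with_seed(recipe$rng_seed, generate_slide_impl(recipe, id))
}

generate_slide_impl <- function(recipe, id) {
  H <- recipe$height_px; W <- recipe$width_px; ps <- recipe$pixel_size

  ## tissue support
  if (recipe$tissue_coverage >= 1) {
    tissue <- matrix(TRUE, H, W)
  } else {
    s <- sqrt(4 * recipe$tissue_coverage / pi)
    a <- s * H / 2; b <- s * W / 2
    rc <- (H + 1) / 2; cc <- (W + 1) / 2
    tissue <- outer(seq_len(H), seq_len(W),
                    function(r, c) ((r - rc) / a)^2 + ((c - cc) / b)^2 <= 1)
  }
  tissue_px <- sum(tissue)

  ## target sizes and placement
  n <- recipe$n_cells
  target_um2 <- runif(n, recipe$area_range[1], recipe$area_range[2])
  target_px <- target_um2 / ps^2
  if (n * recipe$area_range[1] / ps^2 > tissue_px) {
    stop("infeasible packing: n_cells too large for the canvas at area_range",
         call. = FALSE)
  }
  r_target <- sqrt(target_px / pi)
  # shrink separation radii until the discs occupy <= 55% of tissue (random
  # sequential packing stays feasible there)
  pack <- sum(pi * r_target^2) / tissue_px
  r_sep <- r_target * sqrt(min(1, 0.55 / pack))
  ord <- order(-r_sep)
  tissue_idx <- which(tissue)
  placed_r <- numeric(0); placed_c <- numeric(0); placed_sep <- numeric(0)
  for (i in ord) {
    ok <- FALSE
    for (try in seq_len(3000)) {
      pix <- tissue_idx[sample.int(length(tissue_idx), 1)]
      cr <- ((pix - 1) %% H) + 1 + runif(1, -0.5, 0.5)
      cc2 <- ((pix - 1) %/% H) + 1 + runif(1, -0.5, 0.5)
      if (length(placed_r) == 0 ||
          all(sqrt((placed_r - cr)^2 + (placed_c - cc2)^2) >=
              0.75 * (placed_sep + r_sep[i]))) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("infeasible packing: could not place cell after 3000 attempts",
           call. = FALSE)
    }
    placed_r <- c(placed_r, cr); placed_c <- c(placed_c, cc2)
    placed_sep <- c(placed_sep, r_sep[i])
  }

  ## power-diagram tessellation (weights 0.65*r_sep keep each seed inside
  ## its own region for any radius ratio given the 0.75 separation factor)
  w <- (0.65 * placed_sep)^2
  R <- matrix(seq_len(H), H, W)
  C <- matrix(seq_len(W), H, W, byrow = TRUE)
  best <- matrix(Inf, H, W)
  lab <- matrix(0L, H, W)
  for (i in seq_len(n)) {
    d2 <- (R - placed_r[i])^2 + (C - placed_c[i])^2 - w[i]
    win <- d2 < best
    lab[win] <- i
    best[win] <- d2[win]
  }
  lab[!tissue] <- 0L

  ## septa: erode each region by half the septum width
  shift <- function(M, dr, dc) {
    ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
    M[ri, ci, drop = FALSE]
  }
  bnd <- (lab != shift(lab, 1L, 0L)) | (lab != shift(lab, -1L, 0L)) |
    (lab != shift(lab, 0L, 1L)) | (lab != shift(lab, 0L, -1L))
  # close septa along the canvas frame so every lumen is fully enclosed by
  # stained tissue (as on a real section, where the capture frame is chosen
  # inside the tissue)
  bnd[c(1L, H), ] <- TRUE
  bnd[, c(1L, W)] <- TRUE
  septum_half_px <- max(1, recipe$septum_width / (2 * ps))
  dist_bnd <- EBImage::distmap((!bnd) * 1)
  lumen <- dist_bnd >= septum_half_px & lab > 0L & tissue
  truth_labels <- lab
  truth_labels[!lumen] <- 0L

  ## truth stain (noise-free reference labels)
  stain_lab <- matrix(STAIN_BACKGROUND, H, W)
  stain_lab[tissue] <- STAIN_COLLAGEN
  stain_lab[lumen] <- STAIN_LUMEN

  ## plant elastin strokes inside septa
  target_elastin <- round(recipe$elastin_fraction / 100 * tissue_px)
  if (target_elastin > 0) {
    collagen_idx <- which(stain_lab == STAIN_COLLAGEN)
    if (length(collagen_idx) < target_elastin) {
      stop("infeasible recipe: elastin_fraction exceeds available septum area",
           call. = FALSE)
    }
    planted <- 0L
    guard <- 0L
    while (planted < target_elastin) {
      guard <- guard + 1L
      if (guard > 200000L) {
        stop("elastin planting failed to reach the target fraction", call. = FALSE)
      }
      start <- collagen_idx[sample.int(length(collagen_idx), 1)]
      pr <- ((start - 1) %% H) + 1
      pc <- ((start - 1) %/% H) + 1
      theta <- runif(1, 0, 2 * pi)
      len <- sample(15:40, 1)
      misses <- 0L
      for (s in seq_len(len)) {
        ri <- round(pr); ci <- round(pc)
        if (ri >= 1 && ri <= H && ci >= 1 && ci <= W &&
            stain_lab[ri, ci] != STAIN_LUMEN && tissue[ri, ci]) {
          if (stain_lab[ri, ci] == STAIN_COLLAGEN) {
            stain_lab[ri, ci] <- STAIN_ELASTIN
            planted <- planted + 1L
          }
          if (runif(1) < 0.4) {
            rj <- ri + sample(c(-1L, 1L), 1)
            if (rj >= 1 && rj <= H && stain_lab[rj, ci] == STAIN_COLLAGEN) {
              stain_lab[rj, ci] <- STAIN_ELASTIN
              planted <- planted + 1L
            }
          }
          misses <- 0L
        } else {
          misses <- misses + 1L
          if (misses > 3L) break
        }
        if (planted >= target_elastin) break
        pr <- pr + sin(theta); pc <- pc + cos(theta)
        theta <- theta + rnorm(1, 0, 0.25)
      }
    }
  }

  ## render
  img <- array(0, c(H, W, 3))
  pal <- rbind(SYNTH_COLORS$background, SYNTH_COLORS$lumen,
               SYNTH_COLORS$collagen, SYNTH_COLORS$elastin)
  for (k in 1:3) img[, , k] <- matrix(pal[stain_lab + 1L, k], H, W)
  if (recipe$illumination_amp > 0) {
    ill <- 1 + recipe$illumination_amp * (2 * (C - 1) / (W - 1) - 1)
    for (k in 1:3) img[, , k] <- img[, , k] * ill
  }
  if (recipe$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, recipe$noise_sd), dim(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  ## ground-truth cell table
  lum_idx <- which(truth_labels > 0L)
  ids <- truth_labels[lum_idx]
  pr <- ((lum_idx - 1L) %% H) + 1L
  pc <- ((lum_idx - 1L) %/% H) + 1L
  area_px <- tabulate(ids, nbins = n)
  cent_r <- rowsum(as.numeric(pr), ids)[, 1] / area_px[sort(unique(ids))]
  cent_c <- rowsum(as.numeric(pc), ids)[, 1] / area_px[sort(unique(ids))]
  present <- sort(unique(ids))
  # a cell is an edge cell if its full (pre-erosion) region touches the
  # canvas frame or non-tissue pixels
  frame <- matrix(FALSE, H, W)
  frame[c(1L, H), ] <- TRUE; frame[, c(1L, W)] <- TRUE
  near_bg <- frame | !tissue |
    shift(!tissue, 1L, 0L) | shift(!tissue, -1L, 0L) |
    shift(!tissue, 0L, 1L) | shift(!tissue, 0L, -1L)
  edge_ids <- unique(lab[near_bg & lab > 0L])
  truth_cells <- tibble::tibble(
    cell_id = as.integer(present),
    row = cent_r, col = cent_c,
    area_px = as.integer(area_px[present]),
    area_um2 = area_px[present] * ps^2,
    edge = present %in% edge_ids
  )

  cal <- calibrated_image(img, ps, id = id)
  structure(
    list(
      image = cal, tissue = tissue, truth_labels = truth_labels,
      truth_cells = truth_cells,
      truth_stain = structure(
        list(labels = stain_lab, thresholds = color_thresholds(),
             pixel_size = ps),
        class = "stain_map"
      ),
      recipe = recipe
    ),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf(
    "<synthetic_slide '%s'> %d x %d px, %d truth cells, seed %d\n",
    x$image$id, nrow(x$truth_labels), ncol(x$truth_labels),
    nrow(x$truth_cells), x$recipe$rng_seed
  ))
  invisible(x)
}

#' Plant point annotations on a synthetic slide
#'
#' Draws a Poisson-distributed number of events with mean
#' `density x tissue area (mm2)` and scatters them uniformly over tissue
#' pixels — a ground-truth fixture for density normalization.
#'
#' @param slide A `synthetic_slide`.
#' @param category Event category label (e.g. `"mast_cell"`).
#' @param density Expected events per mm2 (`>= 0`).
#' @param rng_seed Integer seed for this draw.
#' @return A tibble of point count records: `slide_id`, `category`, `row`,
#'   `col`.
#' @export
plant_points <- function(slide, category, density, rng_seed = 1) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (density < 0) stop("`density` must be >= 0", call. = FALSE)
  ps <- slide$recipe$pixel_size
  area_mm2 <- sum(slide$tissue) * ps^2 * 1e-6
  withr::with_seed(rng_seed, {
    n <- rpois(1, density * area_mm2)
    idx <- if (n > 0) {
      ti <- which(slide$tissue)
      ti[sample.int(length(ti), n, replace = TRUE)]
    } else integer(0)
    H <- nrow(slide$tissue)
    tibble::tibble(
      slide_id = slide$image$id,
      category = category,
      row = ((idx - 1L) %% H) + 1L,
      col = ((idx - 1L) %/% H) + 1L
    )
  })
}

#' Simulate per-subject mean CSA under a planted pre/post effect
#'
#' Statistical companion to the image generator: for each subject, the
#' pre-treatment per-slide mean is the mean of `n_cells` areas drawn
#' uniformly from `area_range` (the generator's target draw), and the
#' post-treatment mean is the same draw with the range scaled by
#' `1 + effect_pct/100`. Used to study the power of the paired design
#' without rendering images.
#'
#' @param n_subjects Number of paired subjects.
#' @param effect_pct Planted percent change of mean CSA (e.g. 18).
#' @param n_cells Cells averaged per slide.
#' @param area_range Target area range, um2.
#' @param rng_seed Integer seed.
#' @return A tibble: `subject_id`, `mean_pre`, `mean_post`.
#' @export
simulate_subject_means <- function(n_subjects = 9, effect_pct = 18,
                                   n_cells = 200, area_range = c(500, 8700),
                                   rng_seed = 1) {
  withr::with_seed(rng_seed, {
    scale <- 1 + effect_pct / 100
    pre <- vapply(seq_len(n_subjects),
                  function(i) mean(runif(n_cells, area_range[1], area_range[2])),
                  numeric(1))
    post <- vapply(seq_len(n_subjects),
                   function(i) mean(runif(n_cells, scale * area_range[1],
                                          scale * area_range[2])),
                   numeric(1))
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(n_subjects)),
                   mean_pre = pre, mean_post = post)
  })
}

#' Write a synthetic slide to disk
#'
#' Writes the rendered image (PNG), the truth label raster (16-bit TIFF),
#' the truth cell table (CSV) and the recipe (YAML).
#'
#' @param slide A `synthetic_slide`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_slide <- function(slide, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, slide$image$id)
  write_image(slide$image, paste0(base, ".png"))
  write_labels(slide$truth_labels, paste0(base, "_truth_labels.tif"))
  write.csv(as.data.frame(slide$truth_cells),
            paste0(base, "_truth_cells.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(slide$recipe), paste0(base, "_recipe.yaml"))
  invisible(dir)
}
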