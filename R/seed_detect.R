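#' Detect one seed per adipocyte lumen
#'
#' Step 1 of the segmentation algorithm: find a point near the geometric
#' center of every adipocyte. The default detector is deterministic and
#' training-free: it computes the Euclidean distance transform of the
#' lumen class (distance of each lumen pixel to the nearest non-lumen pixel)
#' and keeps its regional maxima, greedily suppressed so that no two seeds
#' lie closer than `min_separation`. A peak's score is its distance value
#' normalized by the largest peak on the slide. An optional trained
#' classifier ([train_seed_classifier()]) can rescore and filter candidates.
#'
#' Equal-height plateau maxima are broken deterministically: the candidate
#' with the smaller `(row, col)` lexicographic index wins.
#'
#' @param stain A [stain_map].
#' @param min_separation Minimum seed separation in micrometres. Default
#'   25 um, roughly the diameter of the smallest reported adipocyte (a
#'   500 um2 circle has diameter ~25 um), so the smallest real cells are
#'   never double-seeded.
#' @param min_radius Minimum distance-transform value (px) for a candidate;
#'   suppresses one-pixel lumen specks (default 2).
#' @param one_per_component Keep only the strongest seed in each connected
#'   lumen component (default `TRUE`). Septa bound every adipocyte, so a
#'   connected unstained region is one cell; elongated lumina can otherwise
#'   carry two distance-transform peaks further apart than `min_separation`.
#' @return A tibble of class `seed_set`: `seed_id`, `row`, `col`, `dist_px`
#'   (distance-transform value at the seed), `score` in `[0, 1]`.
#' @export
detect_seeds <- function(stain, min_separation = 25, min_radius = 2,
                         one_per_component = TRUE) {
  stopifnot(inherits(stain, "stain_map"), min_separation > 0)
  sep_px <- min_separation / stain$pixel_size
  lumen <- stain$labels == STAIN_LUMEN
  empty <- tibble::tibble(
    seed_id = integer(), row = integer(), col = integer(),
    dist_px = numeric(), score = numeric()
  )
  class(empty) <- c("seed_set", class(empty))
  if (!any(lumen)) return(empty)

  dist <- EBImage::distmap(lumen * 1)
  brush_size <- max(3L, 2L * floor(sep_px / 2) + 1L)
  local_max <- EBImage::dilate(dist, EBImage::makeBrush(brush_size, "disc"))
  cand <- which(dist >= min_radius & dist >= local_max - 1e-9, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)

  d <- dist[cand]
  ord <- order(-d, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  d <- d[ord]

  keep_r <- numeric(0); keep_c <- numeric(0); keep_d <- numeric(0)
  sep2 <- sep_px^2
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; cc <- cand[i, 2]
    if (length(keep_r) == 0 ||
        min((keep_r - r)^2 + (keep_c - cc)^2) >= sep2) {
      keep_r <- c(keep_r, r); keep_c <- c(keep_c, cc); keep_d <- c(keep_d, d[i])
    }
  }
  if (one_per_component && length(keep_r) > 0) {
    comp <- EBImage::bwlabel(lumen)
    cid <- comp[cbind(keep_r, keep_c)]
    best <- !duplicated(cid) # candidates already sorted by decreasing peak
    keep_r <- keep_r[best]; keep_c <- keep_c[best]; keep_d <- keep_d[best]
    cid <- cid[best]
    # relocate each seed to its component's geometric center when that pixel
    # still lies in the same lumen component (concave regions keep the peak)
    idx <- which(comp > 0)
    lab_at <- comp[idx]
    rr <- ((idx - 1L) %% nrow(comp)) + 1L
    cc <- ((idx - 1L) %/% nrow(comp)) + 1L
    n_px <- tabulate(lab_at, nbins = max(comp))
    sum_r <- rowsum(as.numeric(rr), lab_at)
    sum_c <- rowsum(as.numeric(cc), lab_at)
    labs_present <- as.integer(rownames(sum_r))
    cent_r <- integer(max(comp)); cent_c <- integer(max(comp))
    cent_r[labs_present] <- as.integer(round(sum_r[, 1] / n_px[labs_present]))
    cent_c[labs_present] <- as.integer(round(sum_c[, 1] / n_px[labs_present]))
    for (k in seq_along(keep_r)) {
      cr <- cent_r[cid[k]]; cc2 <- cent_c[cid[k]]
      if (cr >= 1 && comp[cr, cc2] == cid[k]) {
        keep_r[k] <- cr; keep_c[k] <- cc2
        keep_d[k] <- dist[cr, cc2]
      }
    }
  }
  out <- tibble::tibble(
    seed_id = seq_along(keep_r),
    row = as.integer(keep_r), col = as.integer(keep_c),
    dist_px = keep_d, score = keep_d / max(keep_d)
  )
  class(out) <- c("seed_set", class(out))
  out
}

#' Extract a square patch around a point
#'
#' @param img A [calibrated_image].
#' @param row,col Patch center (1-based).
#' @param half Half-width; the patch is `(2*half+1)` pixels square. Beyond
#'   the image border the edge row/column is replicated, so the requested
#'   point is always the central pixel.
#' @return Numeric array of raw channel values in `[0, 255]`.
#' @export
extract_patch <- function(img, row, col, half = 12) {
  d <- dim(img$pixels)
  ri <- pmin(pmax((row - half):(row + half), 1L), d[1])
  ci <- pmin(pmax((col - half):(col + half), 1L), d[2])
  img$pixels[ri, ci, , drop = FALSE]
}

# Summary features of an RGB patch used by the seed classifier. The center
# of a well-placed seed sits in unstained lumen (bright, unsaturated); the
# features stay deliberately center-local so that cells clipped by the frame
# (half the patch replicated septum) still score as cells.
patch_features <- function(patch) {
  ls <- rgb_lum_sat(patch)
  d <- dim(patch)
  rc <- (d[1] + 1) / 2; cc <- (d[2] + 1) / 2
  rr <- abs(row(ls$lum) - rc); ccd <- abs(col(ls$lum) - cc)
  center <- rr <= 1 & ccd <= 1
  ring <- rr > d[1] / 3 | ccd > d[2] / 3
  lum_center <- mean(ls$lum[center])
  lum_ring <- mean(ls$lum[ring])
  c(
    lum_center = lum_center,
    sat_center = mean(ls$sat[center]),
    lum_ring = lum_ring,
    lum_contrast = lum_center - lum_ring,
    frac_dark = mean(ls$lum <= 80)
  )
}

#' Train a seed-rescoring classifier
#'
#' A random-forest classifier on summary color features of image patches,
#' used as an optional second stage after [detect_seeds()]: candidates
#' scoring below a probability threshold are dropped. Positive patches are
#' centered on cell centers; negatives are off-center or on septa. Training
#' uses a fixed internal seed so repeated fits on the same patches are
#' identical.
#'
#' @param patches A list of patches, each a list with elements `pixels`
#'   (RGB array from [extract_patch()]) and `label` (1 = centered on a cell,
#'   0 = not).
#' @param rng_seed Seed for the forest's bootstrap randomness (default 1).
#' @return An object of class `seed_classifier`.
#' @export
train_seed_classifier <- function(patches, rng_seed = 1) {
  labels <- vapply(patches, function(p) as.numeric(p$label), numeric(1))
  if (sum(labels == 1) < 50 || sum(labels == 0) < 50) {
    stop("need at least 50 positive and 50 negative patches", call. = FALSE)
  }
  feats <- t(vapply(patches, function(p) patch_features(p$pixels), numeric(5)))
  if (all(apply(feats, 2, function(x) max(x) - min(x)) < 1e-12)) {
    stop("degenerate training data: identical features across both classes",
         call. = FALSE)
  }
  df <- as.data.frame(feats)
  fit <- withr::with_seed(rng_seed, randomForest::randomForest(
    x = df, y = factor(labels, levels = c(0, 1)), ntree = 200
  ))
  structure(list(fit = fit, feature_names = colnames(feats)),
            class = "seed_classifier")
}

#' Rescore detected seeds with a trained classifier
#'
#' @param seeds A `seed_set` from [detect_seeds()].
#' @param img The [calibrated_image] the seeds were detected on.
#' @param classifier A [train_seed_classifier()] fit.
#' @param threshold Probability below which a candidate is dropped
#'   (default 0.5).
#' @param half Patch half-width passed to [extract_patch()].
#' @return The filtered `seed_set` with an added `prob` column.
#' @export
rescore_seeds <- function(seeds, img, classifier, threshold = 0.5, half = 12) {
  stopifnot(inherits(classifier, "seed_classifier"))
  if (nrow(seeds) == 0) {
    seeds$prob <- numeric(0)
    return(seeds)
  }
  feats <- t(mapply(
    function(r, cc) patch_features(extract_patch(img, r, cc, half)),
    seeds$row, seeds$col
  ))
  prob <- unname(
    stats::predict(classifier$fit, newdata = as.data.frame(feats),
                   type = "prob")[, "1"]
  )
  out <- seeds[prob >= threshold, , drop = FALSE]
  out$prob <- prob[prob >= threshold]
  out
}

#' Write / read seed tables
#'
#' Seeds round-trip through CSV so users can hand-correct them and feed the
#' corrected file back into segmentation.
#'
#' @param seeds A `seed_set` tibble.
#' @param path CSV path.
#' @param slide_id Identifier written alongside each seed.
#' @return `path` (write) or a `seed_set` tibble (read).
#' @export
write_seeds <- function(seeds, path, slide_id = "slide") {
  df <- data.frame(slide_id = slide_id, row = seeds$row, col = seeds$col,
                   score = seeds$score)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_seeds
#' @export
read_seeds <- function(path) {
  df <- read.csv(path)
  out <- tibble::tibble(
    seed_id = seq_len(nrow(df)),
    row = as.integer(df$row), col = as.integer(df$col),
    dist_px = rep(NA_real_, nrow(df)),
    score = if ("score" %in% names(df)) df$score else rep(1, nrow(df))
  )
  class(out) <- c("seed_set", class(out))
  out
}
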