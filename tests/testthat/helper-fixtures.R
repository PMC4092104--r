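# Shared fixtures, generated once per test run.

# Flat-color calibrated image.
flat_image <- function(rgb, H = 50, W = 50, pixel_size = 1, id = "flat") {
  px <- array(0, c(H, W, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  calibrated_image(px, pixel_size, id = id)
}

# One near-white circular lumen on a pink background.
disk_image <- function(H = 101, W = 101, center = c(51, 51), radius = 30,
                       pixel_size = 1, lumen = c(246, 246, 246),
                       bg = c(231, 146, 180)) {
  d <- sqrt(outer(seq_len(H), rep(1, W)) * 0 +
              (matrix(seq_len(H), H, W) - center[1])^2 +
              (matrix(seq_len(W), H, W, byrow = TRUE) - center[2])^2)
  px <- array(0, c(H, W, 3))
  for (k in 1:3) px[, , k] <- ifelse(d <= radius, lumen[k], bg[k])
  calibrated_image(px, pixel_size, id = "disk")
}

# Memoized small synthetic slide (384 px, 28 cells) reused across files.
small_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_slide(
        slide_recipe(width_px = 384, height_px = 384, n_cells = 28, rng_seed = 7)
      )
    }
    cache
  }
})

# Memoized segmentation of the small slide.
small_segmentation <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- segment_slide(small_slide()$image)
    cache
  }
})
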