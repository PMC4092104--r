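test_that("definitional pixels classify as their stain class", {
  px <- array(0, c(2, 2, 3))
  px[1, 1, ] <- c(0, 0, 0)       # jet black -> elastin
  px[1, 2, ] <- c(250, 250, 250) # near-white -> lumen
  px[2, 1, ] <- c(231, 146, 180) # pink -> collagen
  px[2, 2, ] <- c(120, 80, 95)   # mid-dark pink -> collagen
  img <- calibrated_image(px, 1)
  mask <- structure(list(mask = matrix(TRUE, 2, 2), tissue_area_mm2 = 4e-6,
                         pixel_size = 1), class = "tissue_mask")
  st <- classify_pixels(img, mask)
  expect_identical(st$labels[1, 1], 3L)
  expect_identical(st$labels[1, 2], 1L)
  expect_identical(st$labels[2, 1], 2L)
  expect_identical(st$labels[2, 2], 2L)
})

test_that("classification recovers generator truth with and without noise", {
  sl0 <- generate_slide(slide_recipe(width_px = 384, height_px = 384,
                                     n_cells = 28, noise_sd = 0, rng_seed = 7))
  st0 <- classify_pixels(sl0$image, tissue_mask(sl0$image))
  expect_gte(mean(st0$labels == sl0$truth_stain$labels), 0.98)

  sl <- small_slide() # default noise_sd = 6
  st <- classify_pixels(sl$image, tissue_mask(sl$image))
  expect_gte(mean(st$labels == sl$truth_stain$labels), 0.95)
})

test_that("ECM fractions conserve mass, match plants, and reject empty tissue", {
  # degenerate all-lumen tissue
  img <- flat_image(c(250, 250, 250), 40, 40)
  mask <- structure(list(mask = matrix(TRUE, 40, 40), tissue_area_mm2 = 1600e-6,
                         pixel_size = 1), class = "tissue_mask")
  fr <- ecm_fractions(classify_pixels(img, mask), mask)
  expect_equal(c(fr$pct_collagen, fr$pct_elastin, fr$pct_lumen), c(0, 0, 100))

  # planted elastin fraction on a noise-free slide
  sl <- generate_slide(slide_recipe(width_px = 384, height_px = 384,
                                    n_cells = 28, elastin_fraction = 5,
                                    noise_sd = 0, rng_seed = 19))
  m <- tissue_mask(sl$image)
  fr <- ecm_fractions(classify_pixels(sl$image, m), m)
  truth <- 100 * tabulate(sl$truth_stain$labels + 1L, 4)[2:4] / sum(sl$tissue)
  expect_lt(abs(fr$pct_elastin - 5), 1)
  expect_lt(abs(fr$pct_collagen - truth[2]), 2)
  expect_lt(abs(fr$pct_collagen + fr$pct_elastin + fr$pct_lumen - 100), 1e-6)

  # zero tissue errors
  empty <- structure(list(mask = matrix(FALSE, 4, 4), tissue_area_mm2 = 0,
                          pixel_size = 1), class = "tissue_mask")
  st <- classify_pixels(flat_image(c(255, 255, 255), 4, 4), empty)
  expect_error(ecm_fractions(st, empty), "undefined")
})

test_that("raising the elastin ceiling never decreases the elastin fraction", {
  sl <- small_slide()
  m <- tissue_mask(sl$image)
  prev <- -Inf
  for (ceil in c(40, 80, 120, 160)) {
    fr <- ecm_fractions(
      classify_pixels(sl$image, m, color_thresholds(elastin_lum_max = ceil)), m
    )
    expect_gte(fr$pct_elastin, prev)
    prev <- fr$pct_elastin
  }
})

test_that("fractions are invariant to pixel order (row shuffle)", {
  sl <- small_slide()
  m <- tissue_mask(sl$image)
  fr <- ecm_fractions(classify_pixels(sl$image, m), m)

  perm <- withr::with_seed(1, sample(nrow(sl$image$pixels)))
  px <- sl$image$pixels[perm, , , drop = FALSE]
  msk <- structure(list(mask = m$mask[perm, , drop = FALSE],
                        tissue_area_mm2 = m$tissue_area_mm2, pixel_size = 1),
                   class = "tissue_mask")
  fr2 <- ecm_fractions(classify_pixels(calibrated_image(px, 1), msk), msk)
  expect_equal(fr2$pct_collagen, fr$pct_collagen)
  expect_equal(fr2$pct_elastin, fr$pct_elastin)
  expect_equal(fr2$pct_lumen, fr$pct_lumen)
})

test_that("dimension mismatches are rejected", {
  img <- flat_image(c(250, 250, 250), 10, 10)
  mask <- structure(list(mask = matrix(TRUE, 5, 5), tissue_area_mm2 = 25e-6,
                         pixel_size = 1), class = "tissue_mask")
  expect_error(classify_pixels(img, mask), "dimensions")
})
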