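fifty_cell_slide <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_slide(
        slide_recipe(width_px = 512, height_px = 512, n_cells = 50, rng_seed = 21)
      )
    }
    cache
  }
})

test_that("an image with no lumen yields an empty seed set", {
  img <- flat_image(c(231, 146, 180), 60, 60)
  st <- classify_pixels(img, tissue_mask(img))
  sd <- detect_seeds(st)
  expect_s3_class(sd, "seed_set")
  expect_identical(nrow(sd), 0L)
})

test_that("a single circular lumen yields one seed at its center", {
  img <- disk_image(radius = 30)
  st <- classify_pixels(img, tissue_mask(img))
  sd <- detect_seeds(st)
  expect_identical(nrow(sd), 1L)
  expect_lt(sqrt((sd$row - 51)^2 + (sd$col - 51)^2), 3)
  expect_equal(sd$score, 1)
})

test_that("a 50-cell slide is seeded one-to-one near the true centers", {
  sl <- fifty_cell_slide()
  st <- classify_pixels(sl$image, tissue_mask(sl$image))
  sd <- detect_seeds(st)
  # nearest-neighbour matching of seeds to true centroids within 10 px
  matched <- 0L
  used <- rep(FALSE, nrow(sd))
  for (i in seq_len(nrow(sl$truth_cells))) {
    d <- sqrt((sd$row - sl$truth_cells$row[i])^2 +
                (sd$col - sl$truth_cells$col[i])^2)
    d[used] <- Inf
    if (min(d) <= 10) {
      matched <- matched + 1L
      used[which.min(d)] <- TRUE
    }
  }
  expect_gte(matched, 45)
  expect_lte(nrow(sd) - matched, 2)
})

test_that("seeds shift with the image (translation equivariance)", {
  sl <- small_slide()
  st <- classify_pixels(sl$image, tissue_mask(sl$image))
  sd <- detect_seeds(st)

  dr <- 30L; dc <- 17L
  px <- sl$image$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  shifted <- array(255, dim(px)) # pad with glass
  shifted[(dr + 1):H, (dc + 1):W, ] <- px[1:(H - dr), 1:(W - dc), ]
  st2 <- classify_pixels(calibrated_image(shifted, 1),
                         tissue_mask(calibrated_image(shifted, 1)))
  sd2 <- detect_seeds(st2)

  # compare away from the borders introduced by padding and cropping;
  # the margin must exceed the largest cell radius (~55 px) so that every
  # compared cell survives the shift intact
  inner <- sd$row < H - dr - 70 & sd$col < W - dc - 70 &
    sd$row > 70 & sd$col > 70
  for (i in which(inner)) {
    d <- sqrt((sd2$row - (sd$row[i] + dr))^2 + (sd2$col - (sd$col[i] + dc))^2)
    expect_lte(min(d), 1.5)
  }
})

test_that("no two seeds violate the minimum separation (brute force)", {
  sl <- fifty_cell_slide()
  st <- classify_pixels(sl$image, tissue_mask(sl$image))
  sd <- detect_seeds(st, min_separation = 25, one_per_component = FALSE)
  if (nrow(sd) > 1) {
    D <- as.matrix(dist(cbind(sd$row, sd$col)))
    diag(D) <- Inf
    expect_gte(min(D), 25)
  }
  # and on the noise-free slide, at most one seed lands in each true cell
  sl0 <- generate_slide(slide_recipe(width_px = 384, height_px = 384,
                                     n_cells = 28, noise_sd = 0, rng_seed = 7))
  st0 <- classify_pixels(sl0$image, tissue_mask(sl0$image))
  sd0 <- detect_seeds(st0)
  hit <- sl0$truth_labels[cbind(sd0$row, sd0$col)]
  expect_false(any(duplicated(hit[hit > 0])))
})

make_patches <- function(slide, n_neg = 60, half = 12, seed = 5) {
  img <- slide$image
  pos <- purrr::map(seq_len(nrow(slide$truth_cells)), function(i) {
    list(pixels = extract_patch(img, round(slide$truth_cells$row[i]),
                                round(slide$truth_cells$col[i]), half),
         label = 1)
  })
  septum <- which(slide$truth_stain$labels == 2L)
  H <- nrow(slide$truth_stain$labels)
  idx <- withr::with_seed(seed, sample(septum, n_neg))
  neg <- purrr::map(idx, function(k) {
    list(pixels = extract_patch(img, ((k - 1) %% H) + 1, ((k - 1) %/% H) + 1, half),
         label = 0)
  })
  c(pos, neg)
}

test_that("the patch classifier separates centers from septum and filters nothing true", {
  train <- generate_slide(slide_recipe(width_px = 512, height_px = 512,
                                       n_cells = 60, rng_seed = 31))
  clf <- train_seed_classifier(make_patches(train, n_neg = 70))

  held_out <- small_slide()
  st <- classify_pixels(held_out$image, tissue_mask(held_out$image))
  sd <- detect_seeds(st)
  rs <- rescore_seeds(sd, held_out$image, clf)
  m_raw <- match_seeds(sd, held_out)
  m_rs <- match_seeds(rs, held_out)
  expect_gte(m_rs$precision, 0.9)
  expect_gte(m_rs$recall, 0.9)
  # rescoring at the default threshold loses no matched true center
  expect_identical(m_rs$n_matched, m_raw$n_matched)
})

test_that("classifier training validates its inputs", {
  p1 <- list(pixels = array(128, c(25, 25, 3)), label = 1)
  p0 <- list(pixels = array(128, c(25, 25, 3)), label = 0)
  # too few patches
  expect_error(train_seed_classifier(c(rep(list(p1), 10), rep(list(p0), 60))),
               "at least 50")
  # identical features across both classes
  expect_error(train_seed_classifier(c(rep(list(p1), 60), rep(list(p0), 60))),
               "degenerate")
})

test_that("seed tables round-trip through CSV", {
  sl <- small_slide()
  st <- classify_pixels(sl$image, tissue_mask(sl$image))
  sd <- detect_seeds(st)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_seeds(sd, tmp, slide_id = "s1")
  back <- read_seeds(tmp)
  expect_identical(back$row, sd$row)
  expect_identical(back$col, sd$col)
})
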