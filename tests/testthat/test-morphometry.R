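test_that("areas are calibrated and filtered as specified", {
  lab <- matrix(0L, 120, 120)
  lab[1:100, 1:100] <- 1L # 10,000 px cell
  cells <- measure_cells(lab, pixel_size = 1.0)
  expect_equal(cells$area_um2, 10000)
  expect_true(cells$included)

  cells_half <- measure_cells(lab, pixel_size = 0.5)
  expect_equal(cells_half$area_um2, 2500)

  # 450 um2 cell is excluded by the default 500 um2 floor
  lab2 <- matrix(0L, 40, 40)
  lab2[1:30, 1:15] <- 1L # 450 px
  c2 <- measure_cells(lab2, pixel_size = 1.0)
  expect_equal(c2$area_um2, 450)
  expect_false(c2$included)

  expect_error(measure_cells(lab, pixel_size = 0), "calibration")
  expect_error(measure_cells(lab, 1, min_area = 800, max_area = 700), "min_area")
})

test_that("histograms bin half-open, normalize to one, and reject empties", {
  cells <- tibble::tibble(area_um2 = c(600, 600, 1600),
                          included = c(TRUE, TRUE, TRUE))
  h <- build_histogram(cells, bin_width = 1000, range = c(500, 2500))
  expect_equal(h$freq, c(2 / 3, 1 / 3))
  expect_equal(h$bin_lo, c(500, 1500))

  # boundary values land in the upper bin (half-open [lo, hi))
  hb <- build_histogram(tibble::tibble(area_um2 = c(1500), included = TRUE),
                        bin_width = 1000, range = c(500, 2500))
  expect_equal(hb$freq, c(0, 1))

  big <- tibble::tibble(
    area_um2 = withr::with_seed(2, runif(500, 500, 9999)),
    included = TRUE
  )
  hh <- build_histogram(big)
  expect_lt(abs(sum(hh$freq) - 1), 1e-12)

  expect_error(build_histogram(tibble::tibble(area_um2 = numeric(),
                                              included = logical())), "no included")
})

test_that("paired t handles the null, degenerate, and textbook cases", {
  x <- c(10, 12, 9, 11)
  pt_null <- paired_t(x, x)
  expect_equal(pt_null$mean_difference, 0)
  expect_equal(pt_null$p_value, 1)

  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "degenerate")
  expect_error(paired_t(1:3, 1:4), "lengths")
  expect_error(paired_t(1, 2), "at least 2")

  post <- c(12, 13, 11, 14)
  res <- paired_t(x, post)
  ref <- paired_t_oracle(x, post)
  expect_lt(abs(res$t_statistic - ref$t), 1e-6)
  expect_lt(abs(res$p_value - ref$p), 1e-6)
  expect_equal(res$df, 3)
  expect_equal(res$mean_difference, mean(post - x))

  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$t_statistic, res$t_statistic)
  expect_identical(glance(res), td)
})

test_that("manual-vs-automated validation reproduces exact correlations", {
  expect_equal(validate_against_manual(1:5, 1:5 * 2 + 3)$r, 1)
  expect_equal(validate_against_manual(1:5, 5:1)$r, -1)
  expect_error(validate_against_manual(1:2, 1:2), "at least 3")
  expect_error(validate_against_manual(c(1, 1, 1), 1:3), "zero variance")
  v <- validate_against_manual(c(1, 3, 2, 5), c(2, 3, 2.5, 4))
  ref <- cor.test(c(1, 3, 2, 5), c(2, 3, 2.5, 4))
  expect_equal(v$r, unname(ref$estimate))
  expect_equal(tidy(v)$p_value, ref$p.value)
})

test_that("mean CSA is invariant to relabeling and total area bounded by tissue", {
  sl <- small_slide()
  seg <- small_segmentation()
  cells <- seg$cells
  # relabel: permute cell ids
  perm <- withr::with_seed(3, sample(max(seg$labels)))
  lab2 <- matrix(0L, nrow(seg$labels), ncol(seg$labels))
  nz <- seg$labels > 0
  lab2[nz] <- perm[seg$labels[nz]]
  cells2 <- measure_cells(lab2, 1)
  expect_equal(mean(cells2$area_um2[cells2$included]),
               mean(cells$area_um2[cells$included & cells$converged]),
               tolerance = 1e-9)
  # included area never exceeds tissue area
  expect_lte(sum(cells$area_um2[cells$included]) * 1e-6,
             seg$mask$tissue_area_mm2)
})

test_that("slide summaries aggregate cells and ECM consistently", {
  seg <- small_segmentation()
  s <- summarize_segmentation(seg)
  expect_s3_class(s, "slide_summary")
  expect_equal(s$n_cells_included, sum(seg$cells$included))
  expect_equal(s$mean_csa_um2, mean(seg$cells$area_um2[seg$cells$included]))
  h <- s$histogram[[1]]
  expect_lt(abs(sum(h$freq) - 1), 1e-12)
  expect_equal(s$pct_collagen, seg$ecm$pct_collagen)
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
})
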