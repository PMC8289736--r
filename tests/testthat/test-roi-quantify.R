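# wrap plain summed images into the accumulated container
make_acc <- function(c2, c13, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(c2), ncol(c2))
  structure(list(images = list(C2 = c2, C13C12 = c13), valid = valid,
                 planes = 1L, dwell_time = 10e-3, dead_time = 44e-9,
                 field_size_um = 60),
            class = "accumulated_images")
}

test_that("a homogeneous ROI gives the single-pixel at% value", {
  c2 <- matrix(490, 10, 10); c13 <- matrix(11, 10, 10)
  rois <- matrix(1L, 10, 10)
  r <- roi_quantify(make_acc(c2, c13), rois)
  expect_equal(nrow(r), 1L)
  expect_equal(r$n_pixels, 100L)
  expect_equal(r$atpct, 100 * 11 / 991, tolerance = 1e-12)
  expect_equal(r$sigma_pois, poisson_sigma(100 * 980, 100 * 11))
})

test_that("ROI statistics are ratio-of-sums, not mean of per-pixel ratios", {
  # two-pixel ROI with atomic counts (n13C 0, 20; n12C 1000, 1000):
  # C2 = n12C / 2 per pixel
  c2 <- matrix(c(500, 500), 1, 2)
  c13 <- matrix(c(0, 20), 1, 2)
  rois <- matrix(1L, 1, 2)
  r <- roi_quantify(make_acc(c2, c13), rois, min_pixels = 1L)
  expect_equal(r$atpct, 100 * 20 / 2020, tolerance = 1e-12)
  # mean of per-pixel ratios would be (0 + 100*20/1020)/2 = 0.9804; the
  # ratio of sums must differ from it and sit between the pixel extremes
  expect_false(isTRUE(all.equal(r$atpct, mean(c(0, 100 * 20 / 1020)))))
  expect_gte(r$atpct, 0)
  expect_lte(r$atpct, 100 * 20 / 1020)
})

test_that("ratio-of-sums at% always lies within the per-pixel range", {
  set.seed(14)
  for (i in 1:5) {
    c2 <- matrix(rpois(36, 300), 6, 6)
    c13 <- matrix(rpois(36, 8), 6, 6)
    rois <- matrix(1L, 6, 6)
    r <- roi_quantify(make_acc(c2, c13), rois)
    px <- 100 * c13 / (2 * c2 + c13)
    expect_gte(r$atpct, min(px))
    expect_lte(r$atpct, max(px))
  }
})

test_that("invalid pixels are excluded and fully-invalid ROIs error", {
  c2 <- matrix(100, 4, 8); c13 <- matrix(5, 4, 8)
  c2[, 5:8] <- 9999  # poisoned region that must be masked out
  valid <- matrix(TRUE, 4, 8); valid[, 5:8] <- FALSE
  rois <- matrix(0L, 4, 8)
  rois[, 1:2] <- 1L        # fully valid
  rois[, 4:5] <- 2L        # straddles the invalid boundary
  r <- roi_quantify(make_acc(c2, c13, valid), rois, min_pixels = 1L)
  r1 <- r[r$roi_id == 1, ]
  expect_equal(r1$excluded_fraction, 0)
  expect_equal(r1$atpct, 100 * 5 / 205, tolerance = 1e-12)
  # ROI 2: only the valid column contributes, poisoned counts never leak in
  r2 <- r[r$roi_id == 2, ]
  expect_equal(r2$excluded_fraction, 0.5)
  expect_equal(r2$atpct, r1$atpct, tolerance = 1e-12)
  # a ROI lying entirely in the invalid half is an error
  bad <- matrix(0L, 4, 8); bad[, 7:8] <- 2L
  expect_error(
    roi_quantify(make_acc(c2, c13, valid), bad, min_pixels = 1L),
    "no valid pixel")
})

test_that("undersized ROIs and shape mismatches are rejected", {
  c2 <- matrix(100, 5, 5); c13 <- matrix(5, 5, 5)
  rois <- matrix(0L, 5, 5); rois[1, 1] <- 1L
  expect_error(roi_quantify(make_acc(c2, c13), rois), "below 10 pixels")
  expect_error(roi_quantify(make_acc(c2, c13), matrix(1L, 2, 2)), "shape")
})

test_that("the control reference follows the t-based confidence interval", {
  # constant control values: zero spread, upper bound equals the mean
  ref0 <- build_control_reference(rep(1.08, 5))
  expect_equal(ref0$mean_atpct, 1.08)
  expect_equal(ref0$sd_atpct, 0)
  expect_equal(ref0$upper_bound, 1.08)
  # n = 25, mean 1.08, sd 0.04: upper = 1.08 + t(0.9995, 24) * 0.04 / 5
  set.seed(8)
  x <- as.numeric(scale(rnorm(25))) * 0.04 + 1.08  # exact mean/sd
  ref <- build_control_reference(x)
  expect_equal(ref$mean_atpct, 1.08, tolerance = 1e-12)
  expect_equal(ref$sd_atpct, 0.04, tolerance = 1e-12)
  expect_equal(ref$upper_bound, 1.08 + 3.7453986 * 0.04 / 5,
               tolerance = 1e-6)
  # population mode uses the z-quantile on the single-cell spread
  refp <- build_control_reference(x, mode = "population")
  expect_gt(refp$upper_bound, ref$upper_bound)
  expect_error(build_control_reference(1.08), "at least 2")
})

test_that("enrichment requires both the CI and the 3-sigma criterion", {
  ref <- build_control_reference(rep(c(1.07, 1.09), 13)[1:25])
  ref$mean_atpct <- 1.08; ref$upper_bound <- 1.10  # explicit frozen bounds
  cell <- function(atpct, sigma)
    data.frame(roi_id = 1, atpct = atpct, sigma_pois = sigma)
  expect_true(call_enrichment(cell(7.5, 0.33), ref)$enriched)   # 7.5 > 1.10
  expect_false(call_enrichment(cell(1.08, 0.01), ref)$enriched) # at the mean
  # above the CI bound but sigma too large: criterion 2 fails
  expect_false(call_enrichment(cell(1.5, 0.2), ref)$enriched)
  # monotone: raising atpct never un-enriches, raising sigma never enriches
  expect_true(call_enrichment(cell(9.0, 0.33), ref)$enriched)
  expect_false(call_enrichment(cell(1.5, 0.5), ref)$enriched)
  expect_equal(call_enrichment(cell(7.5, 0.33), ref)$margin, 7.5 - 1.08)
})
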