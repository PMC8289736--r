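small_cells <- function(x, n = 4, rate = 120) {
  data.frame(cy = c(16, 16, 40, 40), cx = c(16, 40, 16, 40),
             a = 6, b = 4, theta = 0, atom_fraction = x,
             carbon_rate = rate)[seq_len(n), ]
}

test_that("simulation is bit-reproducible under a fixed seed", {
  cfg <- synth_nanosims_config(small_cells(0.05), height = 56, width = 56,
                               planes = 3, seed = 9)
  s1 <- simulate_nanosims_stack(cfg)
  s2 <- simulate_nanosims_stack(cfg)
  expect_identical(s1$stack$counts, s2$stack$counts)
  expect_identical(s1$rois, s2$rois)
})

test_that("x = 0 produces no 13C12C ions and a zero at% readout", {
  cfg <- synth_nanosims_config(small_cells(0), height = 56, width = 56,
                               planes = 3, background_rate = 0, seed = 2)
  sim <- simulate_nanosims_stack(cfg)
  expect_true(all(sim$stack$counts$C13C12 == 0))
  res <- nanosims_quantify(sim$stack, sim$rois)
  expect_true(all(res$cells$atpct == 0))
})

test_that("natural-abundance cells read back within 3 sigma of 1.08 at%", {
  cfg <- synth_nanosims_config(small_cells(0.0108, rate = 50), height = 56,
                               width = 56, planes = 10, seed = 3)
  sim <- simulate_nanosims_stack(cfg)
  res <- nanosims_quantify(sim$stack, sim$rois)
  expect_true(all(abs(res$cells$atpct - 1.08) <= 3 * res$cells$sigma_pois))
})

test_that("a drifting acquisition is recovered by alignment but corrupted
          without it", {
  cfg <- synth_nanosims_config(small_cells(0.075), height = 64, width = 64,
                               planes = 6, drift_per_plane = c(1L, 1L),
                               background_rate = 0.5, seed = 4)
  sim <- simulate_nanosims_stack(cfg)
  res <- nanosims_quantify(sim$stack, sim$rois)
  expect_equal(res$drift$dy, 0:5)
  expect_equal(res$drift$dx, 0:5)
  expect_true(all(abs(res$cells$atpct - 7.5) <= 4 * res$cells$sigma_pois))
  # skipping alignment leaves drifted planes mixed into the background:
  # the accumulated CN image inside the ROI is visibly dimmer
  corrected <- dead_time_correct(sim$stack)
  acc_blur <- accumulate_stack(corrected)
  acc_ok <- accumulate_stack(align_planes(corrected)$stack)
  roi <- sim$rois > 0 & acc_ok$valid & acc_blur$valid
  expect_gt(sum(acc_ok$images$CN[roi]), sum(acc_blur$images$CN[roi]))
})

test_that("dead-time distortion simulates undercounting that the correction
          undoes in expectation", {
  cells <- small_cells(0.05, rate = 3000)  # high rate so distortion bites
  cfg_raw <- synth_nanosims_config(cells, height = 56, width = 56,
                                   planes = 4, seed = 5)
  cfg_dt <- synth_nanosims_config(cells, height = 56, width = 56,
                                  planes = 4,
                                  apply_dead_time_distortion = TRUE, seed = 5)
  true_counts <- simulate_nanosims_stack(cfg_raw)$stack
  distorted <- simulate_nanosims_stack(cfg_dt)$stack
  roi <- simulate_nanosims_stack(cfg_raw)$rois > 0
  tsum <- sum(true_counts$counts$C2[, , 1][roi])
  dsum <- sum(distorted$counts$C2[, , 1][roi])
  expect_lt(dsum, tsum)
  csum <- sum(dead_time_correct(distorted)$counts$C2[, , 1][roi])
  expect_lt(abs(csum - tsum) / tsum, 0.005)
})

test_that("overlapping cells are rejected unless explicitly allowed", {
  cells <- data.frame(cy = c(20, 22), cx = c(20, 22), a = 6, b = 4,
                      theta = 0, atom_fraction = 0.05)
  expect_error(simulate_nanosims_stack(
    synth_nanosims_config(cells, height = 40, width = 40, planes = 1)),
    "overlap")
  cfg_ok <- synth_nanosims_config(cells, height = 40, width = 40, planes = 1,
                                  allow_overlap = TRUE)
  expect_silent(simulate_nanosims_stack(cfg_ok))
})

test_that("the end-to-end estimator is unbiased across seeds at both the
          labelled and the natural level", {
  for (x in c(0.075, 0.0108)) {
    means <- vapply(1:4, function(seed) {
      lay <- nanosims_cell_layout(12, x, seed = seed)
      cfg <- synth_nanosims_config(lay$cells, height = lay$height,
                                   width = lay$width, planes = 5, seed = seed)
      sim <- simulate_nanosims_stack(cfg)
      mean(nanosims_quantify(sim$stack, sim$rois)$cells$atpct)
    }, 0)
    expect_lt(max(abs(means - 100 * x) / (100 * x)), 0.01)
  }
})
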