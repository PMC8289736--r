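test_that("the buoyant-density model reproduces its closed form", {
  m <- density_model()
  # gc 0.50, unlabelled: 1.660 + 0.098 * 0.5 = 1.709
  t1 <- synth_taxon("a", gc_content = 0.50)
  expect_equal(buoyant_density(t1, m), 1.709, tolerance = 1e-12)
  # full labelling shifts by exactly full_label_shift
  t2u <- synth_taxon("b", gc_content = 0.37)
  t2l <- synth_taxon("c", gc_content = 0.37, atom_fraction_13C = 1)
  expect_equal(buoyant_density(t2l, m) - buoyant_density(t2u, m), 0.036,
               tolerance = 1e-12)
  # a fully labelled low-GC taxon out-bands an unlabelled high-GC one:
  # the basis of heavy-window detection
  lo_lab <- synth_taxon("d", gc_content = 0.31, atom_fraction_13C = 1)
  hi_unl <- synth_taxon("e", gc_content = 0.65)
  expect_gt(buoyant_density(lo_lab, m), 1.725)
  expect_lt(buoyant_density(hi_unl, m), 1.725)
})

test_that("gradient simulation is seed-reproducible and respects the design", {
  taxa <- sip_scenario_taxa(4, 2, 30, seed = 2)
  cfg <- synth_gradient_config(taxa, seed = 2)
  s1 <- simulate_gradient_experiment(cfg)
  s2 <- simulate_gradient_experiment(cfg)
  expect_identical(s1$table$values, s2$table$values)
  tab <- s1$table
  expect_equal(sort(unique(tab$samples$treatment)), c("C12", "C13"))
  expect_setequal(unique(tab$samples$timepoint_days), c(4, 10, 13, 24))
  expect_equal(sum(tab$samples$treatment == "C13" &
                     tab$samples$timepoint_days == 4), 20L)
  expect_true(all(colSums(tab$values) == 20000))
  expect_equal(length(s1$truth$labelled_asvs), 4L)
})

test_that("empirical fraction compositions converge to the expected
          proportions at high depth", {
  taxa <- sip_scenario_taxa(2, 1, 20, seed = 4)
  cfg <- synth_gradient_config(taxa, depth = 1e6, timepoints = 4L, seed = 4)
  sim <- simulate_gradient_experiment(cfg)
  tab <- normalize_relative_abundance(sim$table)
  c13 <- tab$samples$treatment == "C13"
  emp <- tab$values[, c13]
  expect_lt(max(abs(emp - sim$truth$expected$C13)), 1e-2)
})

test_that("a labelled low-GC taxon dominates heavy windows in the 13C
          treatment only", {
  taxa <- c(list(synth_taxon("lab", "g", gc_content = 0.31,
                             atom_fraction_13C = 0.98,
                             base_abundance = 0.05)),
            lapply(1:40, function(i)
              synth_taxon(sprintf("bg%02d", i), gc_content = 0.3 + i / 100,
                          base_abundance = 0.02)))
  sim <- simulate_gradient_experiment(
    synth_gradient_config(taxa, timepoints = c(4L, 10L, 13L), seed = 6))
  res <- detect_labelled_asvs(sim$table, min_timepoints = 3L)
  lab <- res$summary[res$summary$asv_id == "lab", ]
  expect_true(lab$labelled)
  expect_equal(lab$timepoints_significant, 3L)
})

test_that("with no labelled taxa the treatments are exchangeable: null
          calls are conservative", {
  labelled_total <- 0L
  for (seed in 1:5) {
    taxa <- sip_scenario_taxa(0, 0, 120, seed = seed)
    sim <- simulate_gradient_experiment(
      synth_gradient_config(taxa, seed = seed))
    res <- detect_labelled_asvs(sim$table)
    labelled_total <- labelled_total + sum(res$summary$labelled)
    # per-window false-positive rate bounded by alpha (binomial slack)
    calls <- res$calls
    if (nrow(calls)) {
      rate <- mean(calls$significant)
      n <- nrow(calls)
      expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n))
    }
  }
  expect_equal(labelled_total, 0L)
})

test_that("null p-values are not anti-conservative (one-sided KS)", {
  pvals <- c()
  for (seed in 1:3) {
    taxa <- sip_scenario_taxa(0, 0, 120, seed = seed + 50)
    sim <- simulate_gradient_experiment(
      synth_gradient_config(taxa, seed = seed + 50))
    res <- detect_labelled_asvs(sim$table)
    pvals <- c(pvals, res$calls$p_value)
  }
  expect_gt(length(pvals), 200)
  # ECDF of null p-values must not sit significantly above the diagonal
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the discarded 13C2 species leaves the measured ratio unbiased
          (analytic identity)", {
  # P(12C2) = (1-x)^2, P(13C12C) = 2x(1-x):
  # E[13C12C] / (2 E[12C2] + E[13C12C]) = x for all x
  x <- seq(0.01, 0.99, by = 0.07)
  est <- 2 * x * (1 - x) / (2 * (1 - x)^2 + 2 * x * (1 - x))
  expect_equal(est, x, tolerance = 1e-12)
})
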