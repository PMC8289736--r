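# hand-built gradient table: one heavy window of 4 fractions per treatment
# per timepoint; ASV "sig" is planted high in C13 at days 4, 10 and 13 only
build_gradient_fixture <- function(timepoints = c(4, 10, 13, 24)) {
  d <- c(1.726, 1.730, 1.734, 1.738)
  cols <- list(); meta <- list()
  set.seed(5)
  for (tp in timepoints) {
    for (tr in c("C13", "C12")) {
      hot <- tr == "C13" && tp != 24
      # day 24 uses fixed interleaved ranks so neither direction separates
      sig <- if (hot) 0.20 + runif(4, 0, 0.002)
             else if (tr == "C13") c(0.0100, 0.0110, 0.0120, 0.0130)
             else c(0.0105, 0.0115, 0.0125, 0.0135)
      oth <- 0.05 + runif(4, 0, 0.002)
      ids <- sprintf("%s_d%02d_f%d", tr, tp, 1:4)
      cols[[paste(tr, tp)]] <- rbind(sig = sig, oth = oth,
                                     fill = 1 - sig - oth)
      colnames(cols[[paste(tr, tp)]]) <- ids
      meta[[paste(tr, tp)]] <- data.frame(
        sample_id = ids, gradient_id = paste0(tr, "_", tp), treatment = tr,
        timepoint_days = tp, density = d, replicate = "")
    }
  }
  v <- do.call(cbind, cols)
  abundance_table(v, do.call(rbind, meta), mode = "relative")
}

one_window <- list(window_spec("w1", 1.725, 1.741, 3, 5))

test_that("an ASV significant at three of four timepoints is labelled,
          with a full audit trail", {
  tab <- build_gradient_fixture()
  res <- detect_labelled_asvs(tab, windows = one_window)
  s <- res$summary
  expect_equal(s$asv_id[s$labelled], "sig")
  expect_equal(s$timepoints_significant[s$asv_id == "sig"], 3L)
  expect_equal(unique(s$timepoints_tested), 4L)
  expect_false(s$labelled[s$asv_id == "oth"])
  expect_equal(s$timepoints_significant[s$asv_id == "oth"], 0L)
  # audit trail covers every tested ASV x timepoint for the window
  calls <- res$calls
  expect_true(all(calls$window_name == "w1"))
  expect_setequal(unique(calls$timepoint_days), c(4, 10, 13, 24))
  sig_calls <- calls[calls$asv_id == "sig" & calls$timepoint_days != 24, ]
  expect_true(all(sig_calls$significant))
  expect_true(all(sig_calls$direction == "up"))
})

test_that("a timepoint missing one treatment is skipped with a warning and
          excluded from the denominator", {
  tab <- build_gradient_fixture()
  keep <- !(tab$samples$treatment == "C12" & tab$samples$timepoint_days == 24)
  tab2 <- abundance_table(tab$values[, keep], tab$samples[keep, ],
                          mode = "relative")
  expect_warning(
    res <- detect_labelled_asvs(tab2, windows = one_window),
    "day 24")
  expect_equal(unique(res$summary$timepoints_tested), 3L)
  expect_true(res$summary$labelled[res$summary$asv_id == "sig"])
})

test_that("labelling is monotone in alpha and min_timepoints", {
  tab <- build_gradient_fixture()
  lab_at <- function(alpha, mtp = 3L)
    with(detect_labelled_asvs(tab, windows = one_window, alpha = alpha,
                              min_timepoints = mtp)$summary,
         asv_id[labelled])
  expect_true(all(lab_at(0.01) %in% lab_at(0.05)))
  expect_true(all(lab_at(0.05, mtp = 4L) %in% lab_at(0.05, mtp = 3L)))
  expect_equal(lab_at(0.05, mtp = 4L), character(0))  # sig only at 3 days
})

test_that("the window rule distinguishes any-window from all-window calls", {
  tab <- build_gradient_fixture()
  # second window covers only the two densest fractions plus nothing else:
  # too narrow to ever reach significance with min_fractions 3
  w2 <- list(window_spec("wA", 1.725, 1.741, 3, 5),
             window_spec("wB", 1.729, 1.741, 3, 5))
  any_res <- detect_labelled_asvs(tab, windows = w2, window_rule = "any")
  all_res <- detect_labelled_asvs(tab, windows = w2, window_rule = "all")
  lab_any <- any_res$summary$asv_id[any_res$summary$labelled]
  lab_all <- all_res$summary$asv_id[all_res$summary$labelled]
  expect_true(all(lab_all %in% lab_any))
  expect_true("sig" %in% lab_any)
})

test_that("group aggregation counts labelled ASVs per group and validates
          the mapping", {
  tab <- build_gradient_fixture()
  res <- detect_labelled_asvs(tab, windows = one_window)
  g <- aggregate_group_calls(res$summary,
                             c(sig = "Fusi-like", oth = "other",
                               fill = "other"))
  expect_equal(nrow(g), 1L)
  expect_equal(g$group_id, "Fusi-like")
  expect_equal(g$n_labelled, 1L)
  expect_error(aggregate_group_calls(res$summary, c(oth = "x")), "sig")
  # no labelled ASVs -> empty report
  none <- res$summary; none$labelled <- FALSE
  expect_equal(nrow(aggregate_group_calls(none, c(sig = "g"))), 0L)
  # several labelled ASVs in one group -> single row with the count
  multi <- res$summary
  multi$labelled <- multi$asv_id %in% c("sig", "oth", "fill")
  g3 <- aggregate_group_calls(multi, c(sig = "g1", oth = "g1", fill = "g1"))
  expect_equal(g3$n_labelled, 3L)
})
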