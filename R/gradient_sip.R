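#' Heavy-fraction density window
#'
#' A window selects gradient fractions whose buoyant density falls between
#' `density_min` and `density_max` (both inclusive). Comparisons use between
#' `min_fractions` and `max_fractions` fractions per group; surplus fractions
#' are trimmed to the ones closest to the window midpoint.
#'
#' The two windows used for heavy-fraction screening in anoxic sediment
#' DNA-SIP are 1.725-1.741 g/ml and 1.735-1.746 g/ml; see
#' [default_sip_windows()].
#'
#' @param name window label used in output tables.
#' @param density_min,density_max bounds in g/ml, `density_min < density_max`.
#' @param min_fractions,max_fractions acceptable fraction count per group.
#' @return a `window_spec` object.
#' @export
window_spec <- function(name, density_min, density_max,
                        min_fractions = 3L, max_fractions = 5L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(density_min < density_max))
    stop("density_min must be < density_max")
  min_fractions <- as.integer(min_fractions)
  max_fractions <- as.integer(max_fractions)
  if (min_fractions < 1L || min_fractions > max_fractions)
    stop("need 1 <= min_fractions <= max_fractions")
  structure(list(name = name, density_min = density_min,
                 density_max = density_max, min_fractions = min_fractions,
                 max_fractions = max_fractions),
            class = "window_spec")
}

#' The two heavy-density windows used for DNA-SIP screening
#' @return list of two `window_spec` objects (1.725-1.741 and
#'   1.735-1.746 g/ml, 3-5 fractions each).
#' @export
default_sip_windows <- function() {
  list(window_spec("window1", 1.725, 1.741),
       window_spec("window2", 1.735, 1.746))
}

#' Abundance/prevalence/median filter parameters
#'
#' Cutoffs mirror the serial-group-comparison convention: an ASV enters
#' testing only if (i) its relative abundance exceeds `abundance_cutoff` in
#' at least `ceiling(prevalence_cutoff * n_samples)` of the pooled samples
#' and (ii) its median relative abundance exceeds `max_median_cutoff` in at
#' least one of the two compared groups. All cutoffs are fractions of 1.
#'
#' @param abundance_cutoff per-sample relative abundance threshold
#'   (gradient mode 0.001; microcosm mode 0.05).
#' @param prevalence_cutoff fraction of pooled samples that must exceed
#'   `abundance_cutoff`.
#' @param max_median_cutoff group-median threshold.
#' @param replace_zero if `TRUE`, zeros are replaced by half the smallest
#'   nonzero value of the selected data before filtering/testing; `FALSE`
#'   keeps zeros as zeros.
#' @return a `filter_params` object.
#' @export
filter_params <- function(abundance_cutoff = 0.001, prevalence_cutoff = 0.1,
                          max_median_cutoff = 0.001, replace_zero = FALSE) {
  for (v in c(abundance_cutoff, prevalence_cutoff, max_median_cutoff))
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("cutoffs must lie in [0, 1]")
  structure(list(abundance_cutoff = abundance_cutoff,
                 prevalence_cutoff = prevalence_cutoff,
                 max_median_cutoff = max_median_cutoff,
                 replace_zero = isTRUE(replace_zero)),
            class = "filter_params")
}

#' Microcosm-mode filter defaults (abundance cutoff 0.05)
#' @return a `filter_params` object.
#' @export
microcosm_filter_params <- function() {
  filter_params(abundance_cutoff = 0.05, prevalence_cutoff = 0.1,
                max_median_cutoff = 0.001, replace_zero = FALSE)
}

#' Select gradient fractions falling in a density window
#'
#' Keeps samples of the requested treatment and timepoint whose density lies
#' within the window (bounds inclusive). Errors if fewer than
#' `window$min_fractions` qualify; if more than `window$max_fractions`
#' qualify, the ones closest to the window midpoint are kept, ties broken
#' toward higher density.
#'
#' @param table an `abundance_table` in relative mode with density metadata.
#' @param window a `window_spec`.
#' @param treatment treatment label to keep.
#' @param timepoint timepoint (days) to keep.
#' @return an `abundance_table` restricted to the selected fractions.
#' @export
select_window <- function(table, window, treatment, timepoint) {
  stopifnot(inherits(table, "abundance_table"), inherits(window, "window_spec"))
  if (table$mode != "relative")
    stop("select_window expects a relative-abundance table")
  s <- table$samples
  cand <- s$treatment == treatment & s$timepoint_days == timepoint
  if (any(cand & is.na(s$density)))
    stop("sample(s) without density metadata: ",
         paste(s$sample_id[cand & is.na(s$density)], collapse = ", "))
  inwin <- cand & !is.na(s$density) &
    s$density >= window$density_min & s$density <= window$density_max
  n <- sum(inwin)
  if (n < window$min_fractions)
    stop(sprintf(
      "window '%s' (%s, day %s): %d fraction(s) in [%g, %g], need >= %d",
      window$name, treatment, format(timepoint), n,
      window$density_min, window$density_max, window$min_fractions))
  idx <- which(inwin)
  if (n > window$max_fractions) {
    mid <- (window$density_min + window$density_max) / 2
    d <- s$density[idx]
    ord <- order(abs(d - mid), -d)
    idx <- sort(idx[ord[seq_len(window$max_fractions)]])
  }
  subset_samples_at(table, idx)
}

#' Filter ASVs by abundance, prevalence and group medians
#'
#' @param treat,ctrl `abundance_table`s in relative mode with identical
#'   ASV ids (treatment and control groups of one comparison).
#' @param params a `filter_params` object.
#' @return character vector of retained ASV ids.
#' @export
filter_taxa <- function(treat, ctrl, params = filter_params()) {
  stopifnot(inherits(treat, "abundance_table"),
            inherits(ctrl, "abundance_table"),
            inherits(params, "filter_params"))
  if (!identical(rownames(treat$values), rownames(ctrl$values)))
    stop("treatment and control tables must share identical ASV ids")
  filter_taxa_mat(treat$values, ctrl$values, params)
}

filter_taxa_mat <- function(tv, cv, params) {
  x <- cbind(tv, cv)
  need <- ceiling(params$prevalence_cutoff * ncol(x))
  prev_ok <- rowSums(x > params$abundance_cutoff) >= need
  med_t <- apply(tv, 1, stats::median)
  med_c <- apply(cv, 1, stats::median)
  med_ok <- (med_t > params$max_median_cutoff) |
    (med_c > params$max_median_cutoff)
  rownames(x)[prev_ok & med_ok]
}

# zero replacement: half the smallest nonzero value across the supplied
# matrices, applied to both (the serial-group-comparison "ReplaceZero" option)
replace_zeros <- function(treat_vals, ctrl_vals) {
  pool <- c(treat_vals, ctrl_vals)
  nz <- pool[pool > 0]
  if (!length(nz)) return(list(treat = treat_vals, ctrl = ctrl_vals))
  half <- min(nz) / 2
  treat_vals[treat_vals == 0] <- half
  ctrl_vals[ctrl_vals == 0] <- half
  list(treat = treat_vals, ctrl = ctrl_vals)
}

#' Two-group rank-sum comparison of relative abundances
#'
#' Unpaired two-sided Wilcoxon/Mann-Whitney rank-sum test of treatment
#' versus control values. With `exact = "auto"` the exact null distribution
#' is used when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie correction (and, if
#' `continuity = TRUE`, continuity correction) is used. `exact = "never"`
#' with `continuity = FALSE` reproduces the plain normal-approximation
#' behaviour of the Rhea serial group comparisons (a 3-vs-3 comparison with
#' complete separation then gives p = 0.0495). A paired signed-rank variant
#' (`paired = TRUE`, equal lengths, explicit pairing by position) is
#' available for sensitivity analysis.
#'
#' An enrichment call is one-sided by construction: `significant` requires
#' both `p_value <= alpha` and `direction == "up"`.
#'
#' @param treat_values,ctrl_values numeric vectors (length >= 3 each).
#' @param alpha significance level for the `significant` flag.
#' @param exact `"auto"` or `"never"`.
#' @param continuity apply continuity correction in the normal approximation.
#' @param paired use the paired signed-rank test (requires equal lengths).
#' @return a one-row data.frame: `p_value`, `statistic` (U), `direction`
#'   (`"up"`, `"down"`, `"none"`), `mean_treatment`, `mean_control`,
#'   `n_treatment`, `n_control`, `significant`.
#' @export
compare_groups_wilcoxon <- function(treat_values, ctrl_values, alpha = 0.05,
                                    exact = c("auto", "never"),
                                    continuity = TRUE, paired = FALSE) {
  exact <- match.arg(exact)
  nt <- length(treat_values); nc <- length(ctrl_values)
  if (nt < 3L || nc < 3L)
    stop("need at least 3 values per group (got ", nt, " and ", nc, ")")
  if (paired && nt != nc)
    stop("paired mode requires equal group sizes")
  mt <- mean(treat_values); mc <- mean(ctrl_values)
  all_equal <- length(unique(c(treat_values, ctrl_values))) == 1L
  if (all_equal) {
    return(data.frame(p_value = 1, statistic = nt * nc / 2,
                      direction = "none", mean_treatment = mt,
                      mean_control = mc, n_treatment = nt, n_control = nc,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  ties <- anyDuplicated(c(treat_values, ctrl_values)) > 0L
  use_exact <- exact == "auto" && !ties && (nt + nc) <= 20L
  wt <- suppressWarnings(stats::wilcox.test(
    treat_values, ctrl_values, paired = paired,
    exact = use_exact, correct = continuity,
    alternative = "two.sided"))
  p <- unname(wt$p.value)
  if (is.na(p)) p <- 1  # degenerate variance (e.g. all-tied differences)
  direction <- if (mt > mc) "up" else if (mt < mc) "down" else "none"
  data.frame(p_value = p, statistic = unname(wt$statistic),
             direction = direction, mean_treatment = mt, mean_control = mc,
             n_treatment = nt, n_control = nc,
             significant = (p <= alpha && direction == "up"),
             stringsAsFactors = FALSE)
}

# run the filter + per-ASV rank tests for one treatment/control pair;
# returns the LabelCall audit rows
run_group_comparison <- function(treat, ctrl, params, alpha, timepoint,
                                 window_name, exact, continuity) {
  tv <- treat$values; cv <- ctrl$values
  if (params$replace_zero) {
    rz <- replace_zeros(tv, cv)
    tv <- rz$treat; cv <- rz$ctrl
  }
  keep <- filter_taxa_mat(tv, cv, params)
  if (!length(keep)) return(empty_label_calls())
  rows <- lapply(keep, function(a) {
    res <- compare_groups_wilcoxon(tv[a, ], cv[a, ], alpha = alpha,
                                   exact = exact, continuity = continuity)
    cbind(data.frame(asv_id = a, timepoint_days = timepoint,
                     window_name = window_name, stringsAsFactors = FALSE),
          res)
  })
  do.call(rbind, rows)
}

empty_label_calls <- function() {
  data.frame(asv_id = character(), timepoint_days = integer(),
             window_name = character(), p_value = numeric(),
             statistic = numeric(), direction = character(),
             mean_treatment = numeric(), mean_control = numeric(),
             n_treatment = integer(), n_control = integer(),
             significant = logical(), stringsAsFactors = FALSE)
}

# shared summarisation: per-timepoint significance -> labelled flags
summarise_calls <- function(calls, asv_ids, timepoints_tested, windows,
                            window_rule, min_timepoints) {
  sig_tp <- integer(0)
  names(sig_tp) <- character(0)
  per_asv_sig <- setNames(integer(length(asv_ids)), asv_ids)
  for (tp in timepoints_tested) {
    ctp <- calls[calls$timepoint_days == tp, , drop = FALSE]
    if (!nrow(ctp)) next
    for (a in unique(ctp$asv_id)) {
      ca <- ctp[ctp$asv_id == a, , drop = FALSE]
      sig_by_window <- vapply(windows, function(w) {
        row <- ca[ca$window_name == w, , drop = FALSE]
        nrow(row) > 0 && any(row$significant)
      }, logical(1))
      tp_sig <- if (window_rule == "all") all(sig_by_window)
                else any(sig_by_window)
      if (tp_sig) per_asv_sig[a] <- per_asv_sig[a] + 1L
    }
  }
  out <- data.frame(asv_id = asv_ids,
                    timepoints_significant = unname(per_asv_sig[asv_ids]),
                    timepoints_tested = length(timepoints_tested),
                    stringsAsFactors = FALSE)
  out$labelled <- out$timepoints_significant >= min_timepoints
  out[order(-out$timepoints_significant, out$asv_id), , drop = FALSE]
}

#' Detect 13C-labelled ASVs from density-gradient fraction profiles
#'
#' For each timepoint and each heavy-density window, relative abundances of
#' each ASV across in-window fractions of the 13C treatment are compared
#' against in-window fractions of the 12C control with a two-sided rank-sum
#' test; an ASV is significant at a timepoint if the `window_rule` holds
#' over windows (`"any"`: at least one window; `"all"`: every window), and
#' is called labelled when significant at `min_timepoints` or more
#' timepoints. Only upward shifts (higher mean relative abundance in the
#' 13C treatment) count as significant.
#'
#' @param table an `abundance_table`; counts are normalized internally.
#' @param windows list of `window_spec` (default [default_sip_windows()]).
#' @param timepoints integer vector of timepoints (days) to test; default is
#'   every timepoint present in both treatments.
#' @param params `filter_params` (gradient defaults).
#' @param alpha raw significance level (no multiplicity correction unless
#'   `p_adjust` is set).
#' @param min_timepoints minimum significant timepoints for a labelled call.
#' @param window_rule `"any"` or `"all"`.
#' @param treatment,control treatment labels of the labelled and control
#'   gradients.
#' @param exact,continuity passed to [compare_groups_wilcoxon()].
#' @param p_adjust optional p-adjustment method (e.g. `"BH"`) applied per
#'   timepoint x window before the significance flags are set.
#' @return a list with `summary` (per-ASV data.frame: `asv_id`,
#'   `timepoints_significant`, `timepoints_tested`, `labelled`, sorted by
#'   significant-timepoint count then id) and `calls` (full audit trail, one
#'   row per ASV x window x timepoint tested).
#' @export
detect_labelled_asvs <- function(table, windows = default_sip_windows(),
                                 timepoints = NULL,
                                 params = filter_params(),
                                 alpha = 0.05, min_timepoints = 3L,
                                 window_rule = c("any", "all"),
                                 treatment = "C13", control = "C12",
                                 exact = "auto", continuity = TRUE,
                                 p_adjust = NULL) {
  window_rule <- match.arg(window_rule)
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "counts") table <- normalize_relative_abundance(table)
  s <- table$samples
  if (is.null(timepoints))
    timepoints <- sort(unique(s$timepoint_days[s$treatment %in%
                                                 c(treatment, control)]))
  tested <- integer(0)
  calls <- empty_label_calls()
  for (tp in timepoints) {
    has_t <- any(s$treatment == treatment & s$timepoint_days == tp)
    has_c <- any(s$treatment == control & s$timepoint_days == tp)
    if (!has_t || !has_c) {
      warning(sprintf("day %s lacks the %s treatment; timepoint skipped",
                      format(tp),
                      if (!has_t) treatment else control))
      next
    }
    tested <- c(tested, tp)
    for (w in windows) {
      tw <- select_window(table, w, treatment, tp)
      cw <- select_window(table, w, control, tp)
      calls <- rbind(calls,
                     run_group_comparison(tw, cw, params, alpha, tp, w$name,
                                          exact, continuity))
    }
  }
  if (!is.null(p_adjust) && nrow(calls)) {
    grp <- interaction(calls$timepoint_days, calls$window_name, drop = TRUE)
    calls$p_value <- stats::ave(calls$p_value, grp,
                                FUN = function(p) stats::p.adjust(p, p_adjust))
    calls$significant <- calls$p_value <= alpha & calls$direction == "up"
  }
  summary <- summarise_calls(calls, rownames(table$values), tested,
                             vapply(windows, `[[`, "", "name"),
                             window_rule, min_timepoints)
  list(summary = summary, calls = calls)
}

#' Detect substrate-responsive ASVs in microcosm time series
#'
#' At each timepoint, relative abundances in replicate microcosms of the
#' substrate treatment are compared against the parallel no-substrate
#' controls with the same filter/rank-test machinery as the gradient
#' analysis; an ASV is reported when significant (upward) at
#' `min_timepoints` or more timepoints. With triplicate microcosms the exact
#' rank-sum distribution cannot reach p < 0.1, so this mode defaults to the
#' plain normal approximation without continuity correction, the behaviour
#' of the published serial group comparisons.
#'
#' @param table an `abundance_table` of microcosm samples.
#' @param substrate treatment label of the substrate-amended microcosms.
#' @param control label of the no-substrate controls.
#' @param timepoints timepoints (days) to test; default all shared.
#' @param params `filter_params` ([microcosm_filter_params()] by default).
#' @param alpha significance level.
#' @param min_timepoints minimum significant timepoints (default 2).
#' @param exact,continuity rank-test policy, see
#'   [compare_groups_wilcoxon()].
#' @return as [detect_labelled_asvs()]: list with `summary` and `calls`.
#' @export
detect_substrate_responders <- function(table, substrate,
                                        control = "no_substrate",
                                        timepoints = NULL,
                                        params = microcosm_filter_params(),
                                        alpha = 0.05, min_timepoints = 2L,
                                        exact = "never",
                                        continuity = FALSE) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode == "counts") table <- normalize_relative_abundance(table)
  s <- table$samples
  if (is.null(timepoints))
    timepoints <- sort(unique(s$timepoint_days[s$treatment %in%
                                                 c(substrate, control)]))
  tested <- integer(0)
  calls <- empty_label_calls()
  for (tp in timepoints) {
    it <- which(s$treatment == substrate & s$timepoint_days == tp)
    ic <- which(s$treatment == control & s$timepoint_days == tp)
    if (length(it) < 3L || length(ic) < 3L) {
      warning(sprintf(
        "day %s: need >= 3 replicates per group (got %d vs %d); skipped",
        format(tp), length(it), length(ic)))
      next
    }
    tested <- c(tested, tp)
    calls <- rbind(calls,
                   run_group_comparison(subset_samples_at(table, it),
                                        subset_samples_at(table, ic),
                                        params, alpha, tp, "microcosm",
                                        exact, continuity))
  }
  summary <- summarise_calls(calls, rownames(table$values), tested,
                             "microcosm", "any", min_timepoints)
  list(summary = summary, calls = calls)
}

#' Aggregate labelled-ASV calls to taxon groups
#'
#' @param summary the `summary` data.frame from [detect_labelled_asvs()] or
#'   [detect_substrate_responders()].
#' @param asv_to_group named character vector mapping ASV id to group id.
#'   Every labelled ASV must be mapped.
#' @return data.frame with one row per group containing at least one
#'   labelled ASV: `group_id`, `n_labelled`, `asv_ids` (comma-joined).
#' @export
aggregate_group_calls <- function(summary, asv_to_group) {
  lab <- summary$asv_id[summary$labelled]
  if (!length(lab))
    return(data.frame(group_id = character(), n_labelled = integer(),
                      asv_ids = character(), stringsAsFactors = FALSE))
  unmapped <- lab[!lab %in% names(asv_to_group)]
  if (length(unmapped))
    stop("labelled ASV(s) without group assignment: ",
         paste(unmapped, collapse = ", "))
  grp <- asv_to_group[lab]
  out <- data.frame(group_id = names(table(grp)),
                    n_labelled = as.integer(table(grp)),
                    stringsAsFactors = FALSE)
  out$asv_ids <- vapply(out$group_id, function(g)
    paste(sort(lab[grp == g]), collapse = ","), "")
  out[order(out$group_id), , drop = FALSE]
}
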