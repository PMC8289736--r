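# small builders and independent oracles shared across tests

# tiny abundance table: values matrix + minimal gradient metadata
make_table <- function(values, treatments, timepoints = 4L, densities = NULL,
                       mode = "counts") {
  n <- ncol(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ASV_%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(n))
  abundance_table(values, data.frame(
    sample_id = colnames(values),
    gradient_id = treatments,
    treatment = treatments,
    timepoint_days = rep_len(timepoints, n),
    density = if (is.null(densities)) NA_real_ else densities,
    replicate = "", stringsAsFactors = FALSE), mode = mode)
}

# brute-force exact two-sided rank-sum p-value by enumeration of all
# C(m+n, m) rank assignments (no ties assumed)
bf_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  U_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(m + n, m)
  Us <- colSums(combos) - m * (m + 1) / 2
  p_low <- mean(Us <= U_obs)
  p_high <- mean(Us >= U_obs)
  min(1, 2 * min(p_low, p_high))
}

# a raw stack whose planes are exact integer translations of plane 1
# (zero-filled), for alignment oracles; includes a CN blob for registration
make_translated_stack <- function(h = 24, w = 24, planes = 3, dy = 1, dx = 1,
                                  seed = 42) {
  set.seed(seed)
  cn0 <- matrix(0, h, w)
  cn0[8:14, 9:15] <- matrix(rpois(49, 60), 7, 7)
  c2_0 <- matrix(rpois(h * w, 10), h, w)
  c13_0 <- matrix(rpois(h * w, 2), h, w)
  shift_fill <- function(m, sy, sx) {
    out <- matrix(0, h, w)
    src_r <- which(seq_len(h) - sy >= 1 & seq_len(h) - sy <= h)
    src_c <- which(seq_len(w) - sx >= 1 & seq_len(w) - sx <= w)
    out[src_r, src_c] <- m[src_r - sy, src_c - sx]
    out
  }
  mk <- function(m) {
    a <- array(0, dim = c(h, w, planes))
    for (k in seq_len(planes)) a[, , k] <- shift_fill(m, (k - 1) * dy,
                                                      (k - 1) * dx)
    a
  }
  ion_count_stack(list(C2 = mk(c2_0), C13C12 = mk(c13_0), CN = mk(cn0)))
}
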