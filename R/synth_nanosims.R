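#' Configuration of a synthetic NanoSIMS acquisition
#'
#' Emulates multilayer ion-count imaging of cells on a filter: per pixel and
#' plane the number of C2-family secondary ions is Poisson with the local
#' carbon rate, and each ion is a random pairing of two carbon atoms at the
#' local 13C atom fraction `x`, so the detected species split as
#' P(12C2) = (1-x)^2 and P(13C12C) = 2x(1-x); the 13C2 pairs (probability
#' x^2) are generated and then discarded, since that species is not in the
#' detector set. CN and P channels are Poisson at the cell/background rates.
#' Plane k is translated by (k-1) x `drift_per_plane`. Optional dead-time
#' distortion maps each true count n to round(n / (1 + n * tau / T)),
#' the non-paralyzable detector's observed count (integer, as raw data are).
#'
#' @param cells data.frame with one row per cell: `cy`, `cx` (centre, px),
#'   `a`, `b` (ellipse semi-axes, px), `theta` (orientation, radians),
#'   `atom_fraction` (true 13C atom fraction), and optionally per-cell
#'   `carbon_rate`, `cn_rate`, `p_rate` overriding the global rates.
#' @param height,width image size in pixels.
#' @param planes number of acquisition planes (cycles).
#' @param carbon_rate expected C2-family ions per pixel per plane in cells.
#' @param cn_rate,p_rate expected CN-/P- ions per pixel per plane in cells.
#' @param background_rate expected C2-family ions per background pixel per
#'   plane (substrate carbon at natural abundance).
#' @param background_atom_fraction 13C atom fraction of the background.
#' @param drift_per_plane integer (dy, dx) translation added per plane.
#' @param apply_dead_time_distortion simulate detector undercounting.
#' @param dwell_time,dead_time acquisition constants (seconds).
#' @param allow_overlap permit overlapping cells (default FALSE, error).
#' @param seed RNG seed.
#' @return a `synth_nanosims_config`.
#' @export
synth_nanosims_config <- function(cells, height = 512L, width = 512L,
                                  planes = 10L, carbon_rate = 200,
                                  cn_rate = 150, p_rate = 30,
                                  background_rate = 2,
                                  background_atom_fraction = 0.011,
                                  drift_per_plane = c(0L, 0L),
                                  apply_dead_time_distortion = FALSE,
                                  dwell_time = 10e-3, dead_time = 44e-9,
                                  allow_overlap = FALSE, seed = 1L) {
  cells <- as.data.frame(cells)
  need <- c("cy", "cx", "a", "b", "theta", "atom_fraction")
  if (!all(need %in% names(cells)))
    stop("`cells` needs columns ", paste(need, collapse = ", "))
  if (any(cells$atom_fraction < 0 | cells$atom_fraction > 1))
    stop("atom_fraction must lie in [0, 1]")
  for (r in c("carbon_rate", "cn_rate", "p_rate"))
    if (!r %in% names(cells)) cells[[r]] <- get(r)
  if (any(cells$carbon_rate < 0) || background_rate < 0)
    stop("rates must be non-negative")
  drift_per_plane <- as.integer(drift_per_plane)
  stopifnot(length(drift_per_plane) == 2L)
  structure(list(cells = cells, height = as.integer(height),
                 width = as.integer(width), planes = as.integer(planes),
                 background_rate = background_rate,
                 background_atom_fraction = background_atom_fraction,
                 drift_per_plane = drift_per_plane,
                 apply_dead_time_distortion =
                   isTRUE(apply_dead_time_distortion),
                 dwell_time = dwell_time, dead_time = dead_time,
                 allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "synth_nanosims_config")
}

# ellipse membership mask for one cell, optionally translated
ellipse_mask <- function(h, w, cy, cx, a, b, theta, dy = 0, dx = 0) {
  yy <- matrix(seq_len(h), h, w) - (cy + dy)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - (cx + dx)
  u <- cos(theta) * yy + sin(theta) * xx
  v <- -sin(theta) * yy + cos(theta) * xx
  (u / a)^2 + (v / b)^2 <= 1
}

#' Lay out cells on a grid for a NanoSIMS scenario
#'
#' Places `n_cells` non-overlapping ellipses of ~100 px on a regular grid,
#' all at the same true atom fraction, with slightly varying axes and
#' orientations.
#'
#' @param n_cells number of cells.
#' @param true_atom_fraction the cells' 13C atom fraction.
#' @param spacing_px grid spacing (default 32).
#' @param margin_px border kept free (default 20, room for drift).
#' @param seed RNG seed for the shape jitter.
#' @return list with `cells` (data.frame for [synth_nanosims_config()]) and
#'   `height`/`width` large enough to hold the grid.
#' @export
nanosims_cell_layout <- function(n_cells, true_atom_fraction,
                                 spacing_px = 32L, margin_px = 20L,
                                 seed = 1L) {
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  i <- seq_len(n_cells) - 1L
  cells <- data.frame(
    cy = margin_px + spacing_px / 2 + (i %/% ncol_grid) * spacing_px,
    cx = margin_px + spacing_px / 2 + (i %% ncol_grid) * spacing_px,
    a = stats::runif(n_cells, 6.5, 7.5),
    b = stats::runif(n_cells, 4.2, 4.8),
    theta = stats::runif(n_cells, 0, pi),
    atom_fraction = true_atom_fraction)
  list(cells = cells,
       height = as.integer(2 * margin_px + nrow_grid * spacing_px),
       width = as.integer(2 * margin_px + ncol_grid * spacing_px))
}

#' Simulate a NanoSIMS multilayer ion-count stack with known ground truth
#'
#' @param config a `synth_nanosims_config`.
#' @return list with `stack` (raw `ion_count_stack` with species `C2`,
#'   `C13C12`, `CN`, `P`), `rois` (integer label matrix of the undrifted
#'   cell masks, ROI i = cell row i), `truth` (data.frame of per-cell true
#'   atom fractions plus the discarded 13C2 totals, and the seed).
#' @export
simulate_nanosims_stack <- function(config) {
  stopifnot(inherits(config, "synth_nanosims_config"))
  set.seed(config$seed)
  h <- config$height; w <- config$width; np <- config$planes
  cells <- config$cells
  n_cells <- nrow(cells)
  base_masks <- lapply(seq_len(n_cells), function(i)
    ellipse_mask(h, w, cells$cy[i], cells$cx[i], cells$a[i], cells$b[i],
                 cells$theta[i]))
  rois <- matrix(0L, h, w)
  for (i in seq_len(n_cells)) {
    m <- base_masks[[i]]
    if (!config$allow_overlap && any(rois[m] != 0L))
      stop("cells ", unique(rois[m][rois[m] != 0L])[1], " and ", i,
           " overlap; set allow_overlap = TRUE to permit")
    rois[m] <- i
  }
  species <- c("C2", "C13C12", "CN", "P")
  counts <- lapply(species, function(s) array(0, dim = c(h, w, np)))
  names(counts) <- species
  discarded_13c2 <- numeric(n_cells)
  for (k in seq_len(np)) {
    dy <- (k - 1L) * config$drift_per_plane[1]
    dx <- (k - 1L) * config$drift_per_plane[2]
    crate <- matrix(config$background_rate, h, w)
    cnrate <- matrix(config$background_rate / 4, h, w)
    prate <- matrix(config$background_rate / 10, h, w)
    xmap <- matrix(config$background_atom_fraction, h, w)
    cell_idx <- matrix(0L, h, w)
    for (i in seq_len(n_cells)) {
      m <- ellipse_mask(h, w, cells$cy[i], cells$cx[i], cells$a[i],
                        cells$b[i], cells$theta[i], dy, dx)
      crate[m] <- cells$carbon_rate[i]
      cnrate[m] <- cells$cn_rate[i]
      prate[m] <- cells$p_rate[i]
      xmap[m] <- cells$atom_fraction[i]
      cell_idx[m] <- i
    }
    n_pairs <- stats::rpois(h * w, crate)
    x <- as.vector(xmap)
    c2 <- stats::rbinom(h * w, n_pairs, (1 - x)^2)
    rest <- n_pairs - c2
    p_mixed <- ifelse(x == 0, 1, 2 * x * (1 - x) / (1 - (1 - x)^2))
    c13c12 <- stats::rbinom(h * w, rest, pmin(p_mixed, 1))
    c13c2 <- rest - c13c12
    ci <- as.vector(cell_idx)
    if (any(c13c2 > 0) && any(ci > 0)) {
      agg <- tapply(c13c2[ci > 0], ci[ci > 0], sum)
      discarded_13c2[as.integer(names(agg))] <-
        discarded_13c2[as.integer(names(agg))] + agg
    }
    counts$C2[, , k] <- matrix(c2, h, w)
    counts$C13C12[, , k] <- matrix(c13c12, h, w)
    counts$CN[, , k] <- matrix(stats::rpois(h * w, cnrate), h, w)
    counts$P[, , k] <- matrix(stats::rpois(h * w, prate), h, w)
  }
  if (config$apply_dead_time_distortion) {
    a <- config$dead_time / config$dwell_time
    counts <- lapply(counts, function(v) round(v / (1 + v * a)))
  }
  stack <- ion_count_stack(counts, dwell_time = config$dwell_time,
                           dead_time = config$dead_time,
                           corrected = FALSE)
  truth <- data.frame(roi_id = seq_len(n_cells),
                      true_atom_fraction = cells$atom_fraction,
                      true_atpct = 100 * cells$atom_fraction,
                      discarded_13c2 = discarded_13c2)
  list(stack = stack, rois = rois,
       truth = list(cells = truth, seed = config$seed,
                    drift_per_plane = config$drift_per_plane))
}

#' Canonical labelled-cell and control NanoSIMS scenarios
#'
#' Ready-made configurations for the two single-cell scenarios: `"labelled"`
#' simulates 51 cells at 7.5 at% 13C (the enrichment level reported for
#' sorted 13C-fed cells) and `"control"` simulates 25 cells at 1.08 at%
#' (natural-abundance bacterial biomass). Both use ~100-px elliptical
#' cells, 10 planes and 200 C2-family counts per pixel per plane.
#'
#' @param scenario `"labelled"` or `"control"`.
#' @param seed RNG seed.
#' @param drift_per_plane per-plane drift (default none).
#' @param planes number of planes.
#' @return a `synth_nanosims_config`.
#' @export
nanosims_scenario <- function(scenario = c("labelled", "control"), seed = 1L,
                              drift_per_plane = c(0L, 0L), planes = 10L) {
  scenario <- match.arg(scenario)
  n <- if (scenario == "labelled") 51L else 25L
  x <- if (scenario == "labelled") 0.075 else 0.0108
  lay <- nanosims_cell_layout(n, x, seed = seed)
  synth_nanosims_config(lay$cells, height = lay$height, width = lay$width,
                        planes = planes, drift_per_plane = drift_per_plane,
                        seed = seed)
}
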