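#' Atomic-equivalent carbon counts from C2-family ion images
#'
#' NanoSIMS runs that detect 12C2- and 13C12C- (but not 13C2-) estimate the
#' 13C atom fraction from the printed ratio
#' 13C12C- / (2 x 12C2- + 13C12C-). Under random pairing of carbon atoms
#' into C2- secondary ions this ratio equals the true atom fraction exactly:
#' the mixed-pair 12C atom left out of the denominator compensates the
#' undetected 13C2- pairs. Accordingly the counts entering the estimator are
#' `n13C = C13C12` and `n12C = 2 * C2`, so that
#' `n13C / (n12C + n13C)` reproduces the printed ratio.
#'
#' @param c2_img,c13c12_img matrices (or scalars) of summed 12C2- and
#'   13C12C- counts, same shape, non-negative.
#' @return list with `n12C` and `n13C` (same shape as the inputs).
#' @export
atomic_counts_from_c2 <- function(c2_img, c13c12_img) {
  if (!identical(dim(c2_img), dim(c13c12_img)) ||
      length(c2_img) != length(c13c12_img))
    stop("C2 and C13C12 images must have identical shape")
  if (any(c2_img < 0) || any(c13c12_img < 0))
    stop("ion counts must be non-negative")
  list(n12C = 2 * c2_img, n13C = c13c12_img)
}

#' Per-pixel 13C atom-percent map
#'
#' at% 13C = 100 x n13C / (n12C + n13C). Pixels with zero total carbon are
#' flagged invalid rather than silently set to zero.
#'
#' @param n12C_img,n13C_img matrices of atomic-equivalent counts.
#' @return an `isotope_map`: list with `atpct` (matrix, invalid pixels NA)
#'   and `valid` (logical matrix, denominator > 0).
#' @export
isotope_fraction_map <- function(n12C_img, n13C_img) {
  if (!identical(dim(n12C_img), dim(n13C_img)))
    stop("count images must have identical shape")
  total <- n12C_img + n13C_img
  valid <- total > 0
  atpct <- matrix(NA_real_, nrow = nrow(total), ncol = ncol(total))
  atpct[valid] <- 100 * n13C_img[valid] / total[valid]
  structure(list(atpct = atpct, valid = valid), class = "isotope_map")
}

#' Poisson counting error of the 13C atom fraction
#'
#' Standard error of `n13C / (n12C + n13C)` for Poisson-distributed counts,
#' `sigma = sqrt(n12C^2 * n13C + n13C^2 * n12C) / (n12C + n13C)^2`,
#' expressed in at% units (x 100).
#'
#' @param n12C,n13C numeric scalars or vectors of summed counts;
#'   `n12C + n13C` must be positive.
#' @return sigma in at% units.
#' @export
poisson_sigma <- function(n12C, n13C) {
  if (any(n12C < 0) || any(n13C < 0)) stop("counts must be non-negative")
  total <- n12C + n13C
  if (any(total == 0)) stop("n12C + n13C must be positive")
  100 * sqrt(n12C^2 * n13C + n13C^2 * n12C) / total^2
}

#' Per-cell isotope quantification over ROI label masks
#'
#' For each region of interest, ion counts are summed over the ROI's valid
#' pixels first and the atom fraction and its Poisson error are computed
#' from the summed totals (ratio of sums, not mean of per-pixel ratios — the
#' counting-error formula operates on total counts per object). ROIs
#' overlapping invalid pixels use the valid pixels only; the excluded
#' fraction is reported. A ROI with no valid pixel is an error.
#'
#' @param acc an `accumulated_images` object with species `C2` and `C13C12`.
#' @param rois integer label matrix (0 = background, ROIs = 1..n) of the
#'   same shape as the images.
#' @param min_pixels minimum ROI size in pixels (default 10).
#' @return data.frame, one row per ROI: `roi_id`, `n_pixels`,
#'   `excluded_fraction`, `n12C`, `n13C`, `atpct`, `sigma_pois`.
#' @export
roi_quantify <- function(acc, rois, min_pixels = 10L) {
  stopifnot(inherits(acc, "accumulated_images"))
  if (!all(c("C2", "C13C12") %in% names(acc$images)))
    stop("accumulated images must include C2 and C13C12")
  c2 <- acc$images$C2
  if (!identical(dim(rois), dim(c2)))
    stop("ROI label image shape does not match the ion images")
  if (any(rois < 0) || any(rois != round(rois)))
    stop("ROI labels must be non-negative integers")
  ids <- sort(unique(rois[rois > 0]))
  if (!length(ids)) stop("no ROI labels found")
  small <- ids[vapply(ids, function(i) sum(rois == i), 0L) < min_pixels]
  if (length(small))
    stop("ROI(s) below ", min_pixels, " pixels: ",
         paste(small, collapse = ", "))
  at <- atomic_counts_from_c2(acc$images$C2, acc$images$C13C12)
  rows <- lapply(ids, function(i) {
    px <- rois == i
    ok <- px & acc$valid
    if (!any(ok))
      stop("ROI ", i, " contains no valid pixel")
    n12 <- sum(at$n12C[ok]); n13 <- sum(at$n13C[ok])
    if (n12 + n13 == 0)
      stop("ROI ", i, " has zero total carbon counts")
    data.frame(roi_id = i, n_pixels = sum(px),
               excluded_fraction = 1 - sum(ok) / sum(px),
               n12C = n12, n13C = n13,
               atpct = 100 * n13 / (n12 + n13),
               sigma_pois = poisson_sigma(n12, n13))
  })
  do.call(rbind, rows)
}

#' Natural-abundance control reference for enrichment calls
#'
#' Summarizes single-cell at% 13C values measured on an isotopically
#' unlabelled control culture. The default upper bound is the upper limit of
#' the two-sided `ci_level` Student-t confidence interval of the control
#' mean; `mode = "population"` instead bounds the spread of single-cell
#' values (mean + z-quantile x sd).
#'
#' @param control_atpcts numeric vector of control-cell at% values (n >= 2).
#' @param ci_level confidence level (default 0.999).
#' @param mode `"mean_ci"` or `"population"`.
#' @return a `control_reference`: list with `n_cells`, `mean_atpct`,
#'   `sd_atpct`, `ci_level`, `mode`, `upper_bound`.
#' @export
build_control_reference <- function(control_atpcts, ci_level = 0.999,
                                    mode = c("mean_ci", "population")) {
  mode <- match.arg(mode)
  n <- length(control_atpcts)
  if (n < 2L) stop("need at least 2 control cells")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  m <- mean(control_atpcts)
  s <- stats::sd(control_atpcts)
  q <- 1 - (1 - ci_level) / 2
  upper <- if (mode == "mean_ci") m + stats::qt(q, n - 1) * s / sqrt(n)
           else m + stats::qnorm(q) * s
  structure(list(n_cells = n, mean_atpct = m, sd_atpct = s,
                 ci_level = ci_level, mode = mode, upper_bound = upper),
            class = "control_reference")
}

#' Dual-criterion single-cell 13C enrichment call
#'
#' A cell is significantly enriched when (1) its at% 13C exceeds the upper
#' bound of the control confidence interval AND (2) its statistical counting
#' error (`sigma_mult` x sigma_Pois, default 3 sigma) is smaller than the
#' difference between the cell and the control mean.
#'
#' @param cells data.frame from [roi_quantify()] (columns `atpct`,
#'   `sigma_pois`), or a single-row equivalent.
#' @param control a `control_reference`.
#' @param sigma_mult counting-error multiplier (default 3).
#' @return the `cells` data.frame with columns `margin`
#'   (`atpct - control mean`) and `enriched` appended.
#' @export
call_enrichment <- function(cells, control, sigma_mult = 3) {
  stopifnot(inherits(control, "control_reference"))
  if (!all(c("atpct", "sigma_pois") %in% names(cells)))
    stop("`cells` needs columns atpct and sigma_pois")
  margin <- cells$atpct - control$mean_atpct
  cells$margin <- margin
  cells$enriched <- (cells$atpct > control$upper_bound) &
    (sigma_mult * cells$sigma_pois < margin)
  cells
}

#' Convert delta 13C (per mil, VPDB) to atom percent 13C and back
#'
#' `R = r_vpdb * (delta/1000 + 1)`, `at% = 100 * R / (1 + R)`. The inverse
#' recovers delta exactly. The VPDB reference 13C/12C ratio defaults to the
#' community constant 0.0111802.
#'
#' @param delta_permil delta 13C in per mil; must exceed -1000.
#' @param atpct atom percent 13C in (0, 100).
#' @param r_vpdb reference isotope ratio.
#' @return atom percent (resp. delta per mil).
#' @export
delta_to_atom_percent <- function(delta_permil, r_vpdb = 0.0111802) {
  if (r_vpdb <= 0) stop("r_vpdb must be positive")
  if (any(delta_permil <= -1000))
    stop("delta must exceed -1000 per mil")
  r <- r_vpdb * (delta_permil / 1000 + 1)
  100 * r / (1 + r)
}

#' @rdname delta_to_atom_percent
#' @export
atom_percent_to_delta <- function(atpct, r_vpdb = 0.0111802) {
  if (r_vpdb <= 0) stop("r_vpdb must be positive")
  if (any(atpct <= 0 | atpct >= 100))
    stop("atom percent must lie in (0, 100)")
  r <- atpct / (100 - atpct)
  (r / r_vpdb - 1) * 1000
}

#' End-to-end single-cell NanoSIMS quantification
#'
#' Runs the canonical order of operations on a raw stack: per-plane
#' dead-time correction, integer-pixel drift alignment, stack accumulation,
#' ROI ratio-of-sums quantification and (if a control is supplied) the
#' dual-criterion enrichment call.
#'
#' @param stack a raw (or already corrected) `ion_count_stack`.
#' @param rois integer ROI label matrix.
#' @param control optional `control_reference` or numeric vector of control
#'   at% values.
#' @param ci_level confidence level if `control` is a numeric vector.
#' @param sigma_mult counting-error multiplier for the enrichment call.
#' @param reference_species species used for drift alignment.
#' @param min_pixels minimum ROI size.
#' @return list with `cells` (per-cell results), `drift` (per-plane shifts),
#'   `map` (the accumulated `isotope_map`), `control` (the reference used,
#'   or NULL).
#' @export
nanosims_quantify <- function(stack, rois, control = NULL, ci_level = 0.999,
                              sigma_mult = 3, reference_species = "CN",
                              min_pixels = 10L) {
  stopifnot(inherits(stack, "ion_count_stack"))
  if (!stack$corrected) stack <- dead_time_correct(stack)
  al <- align_planes(stack, reference_species = reference_species)
  acc <- accumulate_stack(al$stack)
  cells <- roi_quantify(acc, rois, min_pixels = min_pixels)
  at <- atomic_counts_from_c2(acc$images$C2, acc$images$C13C12)
  map <- isotope_fraction_map(at$n12C, at$n13C)
  map$valid <- map$valid & acc$valid
  map$atpct[!map$valid] <- NA_real_
  ref <- NULL
  if (!is.null(control)) {
    ref <- if (inherits(control, "control_reference")) control
           else build_control_reference(control, ci_level = ci_level)
    cells <- call_enrichment(cells, ref, sigma_mult = sigma_mult)
  }
  list(cells = cells, drift = al$drift, map = map, control = ref)
}
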