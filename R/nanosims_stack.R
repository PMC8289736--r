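#' NanoSIMS multilayer ion-count image stack
#'
#' Holds per-species ion-count images acquired as sequential planes
#' (cycles) over the same field, together with the acquisition metadata
#' needed for dead-time correction. Species keys follow the detector set of
#' a C- and N-sensitive multicollection run: `C2` (12C2-), `C13C12`
#' (13C12C-), `CN` (12C14N-), `P` (31P-), `S` (32S-), `SE` (secondary
#' electrons). `C2` and `C13C12` are required for isotope analysis.
#'
#' @param counts named list of 3-d arrays `height x width x planes`, one per
#'   species, all the same shape. Raw stacks must be integer-valued.
#' @param dwell_time seconds of beam dwell per pixel per plane (default
#'   10 ms).
#' @param dead_time detector dead time in seconds (default 44 ns).
#' @param field_size_um physical field edge length (default 60).
#' @param corrected has dead-time correction been applied?
#' @param valid logical `height x width x planes` mask of usable pixels
#'   (defaults to all valid); alignment marks out-of-frame pixels invalid.
#' @return an `ion_count_stack` object.
#' @export
ion_count_stack <- function(counts, dwell_time = 10e-3, dead_time = 44e-9,
                            field_size_um = 60, corrected = FALSE,
                            valid = NULL) {
  if (!is.list(counts) || is.null(names(counts)) || any(names(counts) == ""))
    stop("`counts` must be a named list of per-species arrays")
  known <- c("C2", "C13C12", "CN", "P", "S", "SE")
  unknown <- setdiff(names(counts), known)
  if (length(unknown))
    stop("unknown species key(s): ", paste(unknown, collapse = ", "),
         " (expected some of ", paste(known, collapse = ", "), ")")
  dims <- lapply(counts, dim)
  if (any(vapply(dims, length, 0L) != 3L))
    stop("each species array must be height x width x planes")
  if (length(unique(dims)) != 1L)
    stop("species arrays differ in shape/plane count")
  for (sp in names(counts)) {
    a <- counts[[sp]]
    if (anyNA(a) || any(a < 0))
      stop("negative or missing counts in species ", sp)
    if (!corrected && any(a != round(a)))
      stop("raw stack must be integer-valued (species ", sp, ")")
  }
  if (!(dwell_time > dead_time) || dead_time < 0)
    stop("need dwell_time > dead_time >= 0")
  d <- dims[[1]]
  if (is.null(valid)) valid <- array(TRUE, dim = d)
  stopifnot(identical(dim(valid), d))
  structure(list(counts = counts, dwell_time = dwell_time,
                 dead_time = dead_time, field_size_um = field_size_um,
                 corrected = corrected, valid = valid,
                 height = d[1], width = d[2], planes = d[3]),
            class = "ion_count_stack")
}

#' @export
print.ion_count_stack <- function(x, ...) {
  cat(sprintf(
    "ion_count_stack: %dx%d px, %d plane(s), species: %s\n",
    x$height, x$width, x$planes, paste(names(x$counts), collapse = ", ")))
  cat(sprintf("dwell %g s, dead time %g s, %s\n", x$dwell_time, x$dead_time,
              if (x$corrected) "dead-time corrected" else "raw"))
  invisible(x)
}

#' Correct ion counts for detector dead time
#'
#' Applies the non-paralyzable pulse-counting correction per pixel, plane
#' and species: with observed count `m` in a dwell of `T` seconds and dead
#' time `tau`, the corrected count is `m / (1 - m * tau / T)`. Corrected
#' counts are fractional; the stack is flagged so the correction cannot be
#' applied twice.
#'
#' @param stack a raw `ion_count_stack`.
#' @return the corrected stack.
#' @export
dead_time_correct <- function(stack) {
  stopifnot(inherits(stack, "ion_count_stack"))
  if (stack$corrected)
    stop("stack is already dead-time corrected; re-correction forbidden")
  ratio_max <- stack$dead_time / stack$dwell_time
  counts <- lapply(names(stack$counts), function(sp) {
    m <- stack$counts[[sp]]
    loss <- m * ratio_max
    if (any(loss >= 1)) {
      bad <- which(loss >= 1, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "saturated pixel in species %s at (row %d, col %d, plane %d): m*tau/T >= 1",
        sp, bad[1], bad[2], bad[3]))
    }
    m / (1 - loss)
  })
  names(counts) <- names(stack$counts)
  ion_count_stack(counts, dwell_time = stack$dwell_time,
                  dead_time = stack$dead_time,
                  field_size_um = stack$field_size_um,
                  corrected = TRUE, valid = stack$valid)
}

# circular cross-correlation via FFT; returns (dy, dx) maximizing
# sum_x a(x) * b(x - s), i.e. the translation taking b onto a
xcorr_shift <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  idx <- which.max(cc)
  h <- nrow(a); w <- ncol(a)
  dy <- (idx - 1L) %% h
  dx <- (idx - 1L) %/% h
  if (dy > h %/% 2) dy <- dy - h
  if (dx > w %/% 2) dx <- dx - w
  c(dy, dx)
}

# translate a plane by -shift so its content returns to the plane-0 frame;
# out-of-frame source pixels become invalid
shift_plane <- function(img, valid, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- array(0, dim = c(h, w))
  vout <- array(FALSE, dim = c(h, w))
  rows <- seq_len(h); cols <- seq_len(w)
  src_r <- rows + dy; src_c <- cols + dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[rows[ok_r], cols[ok_c]] <- img[src_r[ok_r], src_c[ok_c]]
  vout[rows[ok_r], cols[ok_c]] <- valid[src_r[ok_r], src_c[ok_c]]
  list(img = out, valid = vout)
}

#' Drift-correct the planes of an ion-count stack
#'
#' Estimates an integer-pixel translation of every plane relative to plane 1
#' by maximizing the cross-correlation of the reference-species image
#' (default `CN`, the cellular biomass indicator), then shifts all species
#' identically. Integer shifts preserve counts exactly; pixels whose source
#' falls outside the frame are marked invalid and excluded from
#' accumulation, never wrapped.
#'
#' @param stack an `ion_count_stack`.
#' @param reference_species species used for shift estimation.
#' @return list with `stack` (aligned) and `drift` (data.frame `plane`,
#'   `dy`, `dx`; plane 1 is (0,0)).
#' @export
align_planes <- function(stack, reference_species = "CN") {
  stopifnot(inherits(stack, "ion_count_stack"))
  if (!reference_species %in% names(stack$counts))
    stop("reference species ", reference_species, " not in stack")
  np <- stack$planes
  ref <- stack$counts[[reference_species]]
  shifts <- matrix(0L, nrow = np, ncol = 2)
  if (np > 1L) for (k in 2:np) {
    s <- xcorr_shift(ref[, , k], ref[, , 1])
    if (abs(s[1]) >= stack$height / 2 || abs(s[2]) >= stack$width / 2)
      stop(sprintf("alignment failure: plane %d shift (%d, %d) >= half frame",
                   k, s[1], s[2]))
    shifts[k, ] <- s
  }
  counts <- stack$counts
  valid <- stack$valid
  for (k in seq_len(np)) {
    if (shifts[k, 1] == 0L && shifts[k, 2] == 0L) next
    for (sp in names(counts)) {
      sh <- shift_plane(counts[[sp]][, , k], valid[, , k],
                        shifts[k, 1], shifts[k, 2])
      counts[[sp]][, , k] <- sh$img
    }
    valid[, , k] <- shift_plane(stack$valid[, , k] * 1, stack$valid[, , k],
                                shifts[k, 1], shifts[k, 2])$valid
  }
  aligned <- ion_count_stack(counts, dwell_time = stack$dwell_time,
                             dead_time = stack$dead_time,
                             field_size_um = stack$field_size_um,
                             corrected = stack$corrected, valid = valid)
  list(stack = aligned,
       drift = data.frame(plane = seq_len(np), dy = shifts[, 1],
                          dx = shifts[, 2]))
}

#' Accumulate a stack into per-species summed images
#'
#' Pixel-wise sum over planes, restricted to pixels valid in every plane
#' (so drift-trimmed margins never mix partial plane counts); the combined
#' validity mask is propagated.
#'
#' @param stack an aligned, dead-time-corrected `ion_count_stack`.
#' @return an `accumulated_images` object: list with `images` (named list of
#'   `height x width` matrices), `valid` (logical matrix) and the
#'   acquisition metadata.
#' @export
accumulate_stack <- function(stack) {
  stopifnot(inherits(stack, "ion_count_stack"))
  valid_all <- apply(stack$valid, c(1, 2), all)
  images <- lapply(stack$counts, function(a) {
    s <- apply(a, c(1, 2), sum)
    s[!valid_all] <- 0
    s
  })
  structure(list(images = images, valid = valid_all,
                 planes = stack$planes, dwell_time = stack$dwell_time,
                 dead_time = stack$dead_time,
                 field_size_um = stack$field_size_um),
            class = "accumulated_images")
}
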