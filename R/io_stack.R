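#' Write an ion-count stack as per-species multi-page TIFFs plus a manifest
#'
#' Each species becomes one multi-page TIFF (pages = planes); counts are
#' stored as 32-bit unsigned integers for raw stacks. A JSON manifest maps
#' species to files and carries the acquisition metadata
#' (`dwell_time_s`, `dead_time_s`, `field_size_um`, `corrected`). Corrected
#' (fractional) stacks are not written: the interchange format is raw data.
#'
#' @param stack a raw `ion_count_stack`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return path of the manifest JSON, invisibly.
#' @export
write_ion_stack <- function(stack, dir, prefix = "stack") {
  stopifnot(inherits(stack, "ion_count_stack"))
  if (stack$corrected)
    stop("only raw (integer) stacks are written to TIFF")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scale <- 2^32 - 1
  files <- list()
  for (sp in names(stack$counts)) {
    a <- stack$counts[[sp]]
    if (any(a > scale)) stop("counts exceed 32-bit range in species ", sp)
    pages <- lapply(seq_len(stack$planes), function(k) a[, , k] / scale)
    f <- file.path(dir, sprintf("%s_%s.tif", prefix, sp))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L,
                    compression = "deflate", reduce = FALSE)
    files[[sp]] <- basename(f)
  }
  manifest <- list(species = files,
                   planes = stack$planes, height = stack$height,
                   width = stack$width,
                   dwell_time_s = stack$dwell_time,
                   dead_time_s = stack$dead_time,
                   field_size_um = stack$field_size_um,
                   corrected = FALSE, count_scale = scale)
  mpath <- file.path(dir, sprintf("%s_manifest.json", prefix))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read an ion-count stack from a manifest written by [write_ion_stack()]
#'
#' @param manifest_path path to the stack manifest JSON.
#' @return a raw `ion_count_stack`.
#' @export
read_ion_stack <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  scale <- if (!is.null(m$count_scale)) m$count_scale else 2^32 - 1
  counts <- list()
  for (sp in names(m$species)) {
    pages <- tiff::readTIFF(file.path(dir, m$species[[sp]]), all = TRUE)
    if (length(pages) != m$planes)
      stop(sprintf("species %s has %d plane(s), manifest says %d",
                   sp, length(pages), m$planes))
    a <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                          length(pages)))
    for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * scale)
    counts[[sp]] <- a
  }
  dims <- unique(lapply(counts, dim))
  if (length(dims) != 1L)
    stop("species TIFFs differ in shape or plane count")
  if (isTRUE(m$corrected))
    stop("manifest flags a corrected stack; raw integer data expected")
  ion_count_stack(counts, dwell_time = m$dwell_time_s,
                  dead_time = m$dead_time_s,
                  field_size_um = if (is.null(m$field_size_um)) 60
                                  else m$field_size_um,
                  corrected = FALSE)
}

#' Read / write a ROI label image (16-bit TIFF)
#' @param path TIFF path.
#' @return integer label matrix.
#' @export
read_roi_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  matrix(as.integer(round(img * (2^16 - 1))), nrow(img), ncol(img))
}

#' @rdname read_roi_tiff
#' @param rois integer label matrix (values < 2^16).
#' @export
write_roi_tiff <- function(rois, path) {
  if (any(rois < 0) || any(rois >= 2^16))
    stop("ROI labels must fit 16-bit unsigned range")
  tiff::writeTIFF(rois / (2^16 - 1), path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' Write an at% map as a 32-bit TIFF (values scaled to [0, 1] = 0-100 at%)
#' @param map an `isotope_map`.
#' @param path TIFF path.
#' @export
write_isotope_map_tiff <- function(map, path) {
  stopifnot(inherits(map, "isotope_map"))
  img <- map$atpct / 100
  img[!map$valid] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

#' Run manifest capturing parameters, inputs and seed of a run
#'
#' @param command the (sub)command executed.
#' @param params named list of all parameters.
#' @param inputs character vector of input file paths (MD5-digested).
#' @param seed RNG seed used, or NA.
#' @param path where to write the JSON (optional).
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(command, params = list(), inputs = character(),
                         seed = NA_integer_, path = NULL) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  m <- list(tool = "sipsims",
            version = as.character(utils::packageVersion("sipsims")),
            command = command, parameters = params,
            input_digests = digests, seed = seed,
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(m))
  }
  m
}
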