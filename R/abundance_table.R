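#' ASV abundance table with gradient/microcosm sample metadata
#'
#' The central container for amplicon profiles: a numeric matrix of ASV
#' abundances (rows = ASVs, columns = samples) plus a per-sample metadata
#' data frame. Samples are either CsCl gradient fractions (carrying a
#' buoyant density in g/ml) or microcosm sediment samples.
#'
#' @param values numeric matrix, ASVs x samples, non-negative. Row names are
#'   used as ASV ids if `asv_ids` is missing; column names as sample ids.
#' @param samples data.frame with one row per sample column; must contain
#'   `sample_id` and `treatment`; `gradient_id`, `timepoint_days`, `density`
#'   and `replicate` are filled with defaults when absent. `density` is the
#'   fraction buoyant density in g/ml (NA allowed for microcosm samples).
#' @param mode `"counts"` (raw reads) or `"relative"` (column proportions).
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `samples`, `mode`.
#' @examples
#' tab <- abundance_table(
#'   matrix(c(10, 30, 60, 5, 5, 90), nrow = 3,
#'          dimnames = list(paste0("ASV_", 1:3), c("s1", "s2"))),
#'   data.frame(sample_id = c("s1", "s2"), treatment = c("C13", "C12"),
#'              timepoint_days = 4, density = c(1.73, 1.73)))
#' normalize_relative_abundance(tab)
#' @export
abundance_table <- function(values, samples, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (ASVs x samples)")
  if (is.null(rownames(values)))
    stop("`values` must have ASV ids as row names")
  if (is.null(colnames(values)))
    stop("`values` must have sample ids as column names")
  if (anyNA(values) || any(values < 0))
    stop("abundances must be non-negative and non-missing")
  if (anyDuplicated(rownames(values)))
    stop("duplicate ASV ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "treatment") %in% names(samples)))
    stop("`samples` needs at least columns sample_id and treatment")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in metadata")
  if (!"gradient_id" %in% names(samples)) samples$gradient_id <- ""
  if (!"timepoint_days" %in% names(samples)) samples$timepoint_days <- 0L
  if (!"density" %in% names(samples)) samples$density <- NA_real_
  if (!"replicate" %in% names(samples)) samples$replicate <- ""
  if (any(samples$timepoint_days < 0, na.rm = TRUE))
    stop("timepoint_days must be >= 0")
  if (any(!is.na(samples$density) & samples$density <= 1.0))
    stop("density must exceed 1.0 g/ml")
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta))
    stop("no metadata for sample(s): ", paste(missing_meta, collapse = ", "))
  extra_meta <- setdiff(samples$sample_id, colnames(values))
  if (length(extra_meta))
    stop("metadata rows without matching sample column: ",
         paste(extra_meta, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (mode == "relative") {
    cs <- colSums(values)
    if (any(cs == 0))
      stop("all-zero sample column(s): ",
           paste(colnames(values)[cs == 0], collapse = ", "))
    if (any(abs(cs - 1) > 1e-9))
      stop("relative-mode columns must sum to 1 (max deviation ",
           format(max(abs(cs - 1))), ")")
  }
  structure(list(values = values, samples = samples, mode = mode),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d ASVs x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("treatments:",
      paste(names(table(x$samples$treatment)), collapse = ", "), "\n")
  tp <- sort(unique(x$samples$timepoint_days))
  cat("timepoints (days):", paste(tp, collapse = ", "), "\n")
  if (any(!is.na(x$samples$density)))
    cat(sprintf("density range: %.4f-%.4f g/ml\n",
                min(x$samples$density, na.rm = TRUE),
                max(x$samples$density, na.rm = TRUE)))
  invisible(x)
}

#' Convert a count table to per-sample relative abundances
#'
#' Each sample column is divided by its total so columns sum to one. Zero
#' counts stay exactly zero; any zero-replacement policy is applied
#' downstream (see `filter_params(replace_zero=)`), matching the convention
#' of serial group comparison pipelines.
#'
#' @param table an `abundance_table` in `"counts"` mode.
#' @return The table in `"relative"` mode.
#' @export
normalize_relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$mode != "counts")
    stop("table is already in relative mode")
  cs <- colSums(table$values)
  if (any(cs == 0))
    stop("cannot normalize all-zero sample column(s): ",
         paste(colnames(table$values)[cs == 0], collapse = ", "))
  vals <- sweep(table$values, 2, cs, "/")
  abundance_table(vals, table$samples, mode = "relative")
}

#' Subset an abundance table by sample
#' @param table an `abundance_table`.
#' @param idx logical or integer index over sample columns.
#' @return an `abundance_table` with the selected samples.
#' @keywords internal
subset_samples_at <- function(table, idx) {
  abundance_table(table$values[, idx, drop = FALSE],
                  table$samples[idx, , drop = FALSE],
                  mode = table$mode)
}

#' Read an abundance table and its sample metadata from TSV
#'
#' The table file has ASVs as rows (first column `asv_id`) and samples as
#' columns; the metadata file has columns `sample_id`, `gradient_id`,
#' `treatment`, `timepoint_days`, `density`, `replicate`. Both are
#' tab-separated, UTF-8, '.' decimal.
#'
#' @param path path to the abundance TSV.
#' @param meta_path path to the sample metadata TSV.
#' @param mode `"counts"` or `"relative"`.
#' @return an `abundance_table`.
#' @export
read_abundance_table <- function(path, meta_path, mode = "counts") {
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!ncol(raw) >= 2) stop("abundance TSV needs an asv_id column plus samples")
  asv_ids <- as.character(raw[[1]])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric abundance values in ", path)
  rownames(vals) <- asv_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  abundance_table(vals, meta, mode = mode)
}

#' Write an abundance table and its metadata to TSV
#' @param table an `abundance_table`.
#' @param path abundance TSV path (rows ASVs, first column `asv_id`).
#' @param meta_path metadata TSV path.
#' @return invisibly, the input table.
#' @export
write_abundance_table <- function(table, path, meta_path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(asv_id = rownames(table$values), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(table$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(table)
}
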