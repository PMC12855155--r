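# Readers, writers and slicing for SGB count matrices and study metadata.

DIET_LEVELS <- c("F", "G")
FE_LEVELS <- c("HFE", "LFE")
TIMEPOINT_LEVELS <- c("D1", "D80", "D100", "D180")

#' Normalize a timepoint token
#'
#' Maps the various spellings used in study designs ("Day 1", "day80", "1",
#' "D1") onto the canonical tokens `D1`, `D80`, `D100`, `D180`.
#'
#' @param x character vector of timepoint labels.
#' @return character vector of canonical tokens.
#' @examples
#' normalize_timepoint(c("Day 1", "D80", "day 100", "180"))
#' @export
normalize_timepoint <- function(x) {
  x <- trimws(as.character(x))
  key <- toupper(gsub("[[:space:]_]+", "", x))
  key <- sub("^DAY", "D", key)
  key <- ifelse(grepl("^[0-9]+$", key), paste0("D", key), key)
  bad <- !(key %in% TIMEPOINT_LEVELS)
  if (any(bad)) {
    stop("unknown timepoint label(s): ", paste(unique(x[bad]), collapse = ", "),
         " (expected one of ", paste(TIMEPOINT_LEVELS, collapse = ", "), ")",
         call. = FALSE)
  }
  key
}

#' Validate an SGB-by-sample count matrix
#'
#' A count matrix is a plain integer-valued matrix with SGB identifiers as
#' row names and sample identifiers as column names.  Validation enforces
#' non-negative integer cells and unique identifiers.
#'
#' @param counts numeric matrix, SGBs in rows, samples in columns.
#' @return the matrix, invisibly, with storage mode set to integer-valued
#'   double preserved as-is.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix", call. = FALSE)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must carry SGB row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate SGB identifiers in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample identifiers in count matrix", call. = FALSE)
  if (length(counts)) {
    if (any(!is.finite(counts)))
      stop("count matrix contains non-finite cells", call. = FALSE)
    if (any(counts < 0))
      stop("count matrix contains negative cells", call. = FALSE)
    if (any(counts != round(counts)))
      stop("count matrix contains non-integer cells", call. = FALSE)
  }
  invisible(counts)
}

#' Read an SGB-by-sample count matrix from TSV
#'
#' Expects a tab-delimited file whose first column holds SGB identifiers
#' (header cell ignored) and whose remaining header cells are sample
#' identifiers; the body must be non-negative integers.
#'
#' @param path path to a tab-delimited text file.
#' @return integer matrix (SGBs x samples) with identifier dimnames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("count matrix file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "")
  if (ncol(tab) < 1L) stop("count matrix has no columns: ", path,
                           call. = FALSE)
  sgb_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sgb_ids))
    stop("duplicate SGB identifiers in ", path, call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers in ", path, call. = FALSE)
  body <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body),
                                 ncol = ncol(body)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(body) && nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "count matrix %s: cell (row %d [%s], col %d [%s]) = \"%s\" is not a non-negative integer",
      path, i, sgb_ids[i], j, sample_ids[j], body[i, j]), call. = FALSE)
  }
  counts <- matrix(num, nrow = length(sgb_ids), ncol = length(sample_ids),
                   dimnames = list(sgb_ids, sample_ids))
  validate_count_matrix(counts)
  counts
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()]: tab-delimited, first header cell
#' `sgb_id`, no quoting.
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  validate_count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sgb_id", colnames(counts)), collapse = "\t"), con)
  if (nrow(counts)) {
    body <- apply(counts, 2L, function(x) format(x, scientific = FALSE,
                                                 trim = TRUE))
    body <- matrix(body, nrow = nrow(counts))
    writeLines(paste(rownames(counts),
                     apply(body, 1L, paste, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Requires columns `sample_id`, `animal_id`, `diet` (F/G), `fe_group`
#' (HFE/LFE) and `timepoint` (normalized to D1/D80/D100/D180).
#'
#' @param path path to a CSV file.
#' @return data frame with one validated record per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  md <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_sample_metadata(md)
}

#' Validate sample metadata
#'
#' @param md data frame with columns `sample_id`, `animal_id`, `diet`,
#'   `fe_group`, `timepoint`.
#' @return the validated data frame with timepoints normalized.
#' @export
validate_sample_metadata <- function(md) {
  need <- c("sample_id", "animal_id", "diet", "fe_group", "timepoint")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (any(!(md$diet %in% DIET_LEVELS)))
    stop("unknown diet level(s): ",
         paste(setdiff(md$diet, DIET_LEVELS), collapse = ", "),
         " (expected F or G)", call. = FALSE)
  if (any(!(md$fe_group %in% FE_LEVELS)))
    stop("unknown fe_group level(s): ",
         paste(setdiff(md$fe_group, FE_LEVELS), collapse = ", "),
         " (expected HFE or LFE)", call. = FALSE)
  md$timepoint <- normalize_timepoint(md$timepoint)
  key <- paste(md$animal_id, md$timepoint, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (animal_id, timepoint) pairs in metadata", call. = FALSE)
  md
}

#' Read an SGB taxonomy table
#'
#' Tab-delimited with columns `sgb_id` and `lineage`, the latter a
#' GTDB-style string of up to 7 semicolon-separated ranks
#' (`d__...;p__...;...;g__...;s__...`).  The genus token is extracted with
#' its `g__` prefix stripped.
#'
#' @param path path to a TSV file.
#' @return data frame with columns `sgb_id`, `lineage`, `genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path,
                               call. = FALSE)
  tax <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  need <- c("sgb_id", "lineage")
  miss <- setdiff(need, colnames(tax))
  if (length(miss))
    stop("taxonomy missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_taxonomy(tax)
}

#' Validate a taxonomy table and extract genus tokens
#'
#' @param tax data frame with `sgb_id` and `lineage` columns.
#' @return data frame with a `genus` column added (empty string when the
#'   genus rank is missing).
#' @export
validate_taxonomy <- function(tax) {
  if (anyDuplicated(tax$sgb_id))
    stop("duplicate sgb_id in taxonomy", call. = FALSE)
  ranks <- strsplit(tax$lineage, ";", fixed = TRUE)
  if (any(lengths(ranks) > 7L))
    stop("lineage with more than 7 ranks in taxonomy", call. = FALSE)
  tax$genus <- vapply(ranks, function(r) {
    g <- r[grepl("^\\s*g__", r)]
    if (length(g)) sub("^\\s*g__", "", trimws(g[1L]))
    else if (length(r) >= 6L) trimws(r[6L])
    else ""
  }, character(1L))
  tax
}

#' Subset a count matrix to one group-timepoint slice
#'
#' Selects the sample columns matching a feed-efficiency group and
#' timepoint (optionally also a diet).  SGB rows are retained even when
#' all-zero within the slice; dropping undetected taxa is the model
#' fitter's decision, not the slicer's.
#'
#' @param counts validated count matrix.
#' @param metadata validated sample metadata.
#' @param fe_group `"HFE"` or `"LFE"`.
#' @param timepoint timepoint label (normalized via
#'   [normalize_timepoint()]).
#' @param diet optional diet filter, `"F"` or `"G"`.
#' @return count matrix restricted to the matching sample columns.
#' @export
slice_group_timepoint <- function(counts, metadata, fe_group, timepoint,
                                  diet = NULL) {
  validate_count_matrix(counts)
  metadata <- validate_sample_metadata(metadata)
  fe_group <- match.arg(fe_group, FE_LEVELS)
  timepoint <- normalize_timepoint(timepoint)
  keep <- metadata$fe_group == fe_group & metadata$timepoint == timepoint
  if (!is.null(diet)) {
    diet <- match.arg(diet, DIET_LEVELS)
    keep <- keep & metadata$diet == diet
  }
  ids <- metadata$sample_id[keep]
  ids <- ids[ids %in% colnames(counts)]
  if (length(ids) == 0L)
    stop("no samples match slice (", fe_group, ", ", timepoint,
         if (!is.null(diet)) paste0(", diet ", diet), ")", call. = FALSE)
  if (length(ids) == 1L)
    stop("slice (", fe_group, ", ", timepoint,
         ") resolves to a single sample; >=2 replicates required",
         call. = FALSE)
  animals <- metadata$animal_id[match(ids, metadata$sample_id)]
  if (length(unique(animals)) < 2L)
    stop("slice (", fe_group, ", ", timepoint,
         ") contains fewer than 2 distinct animals", call. = FALSE)
  counts[, ids, drop = FALSE]
}

#' Write a JSON run manifest
#'
#' Records the calling context of an analysis run: parameters, input file
#' digests, seed and package version.  Every file-producing entry point in
#' the package emits one of these next to its outputs.
#'
#' @param path output JSON path.
#' @param step short name of the analysis step.
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (digested when they
#'   exist).
#' @param seed integer seed used, or `NULL` for deterministic steps.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, step, params = list(),
                               inputs = character(), seed = NULL) {
  digest <- vapply(inputs, function(f) {
    if (file.exists(f)) unname(tools::md5sum(f)) else NA_character_
  }, character(1L))
  manifest <- list(
    step = step,
    parameters = params,
    inputs = as.list(digest),
    seed = seed,
    package = "rumenassembly",
    version = as.character(utils::packageVersion("rumenassembly")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
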