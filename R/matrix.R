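# Phosphopeptide intensity matrix: construction, validation and tabular I/O.
#
# Intensities are nonnegative spectral intensities; an exact 0 means "not
# detected". No NA state is kept: missing cells in input tables are read
# as 0, matching the not-detected semantics the downstream zero -> 1
# substitution rule presupposes.

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.WINDOW_WIDTH <- 15L
.WINDOW_CENTER <- 8L
.PEPTIDE_COLS <- c("peptide_id", "protein_ids", "residue", "site_position",
                   "sequence_window")

#' Construct a phosphopeptide intensity matrix
#'
#' Bundles a nonnegative peptide-by-sample intensity matrix with per-peptide
#' site annotations. Zero intensity means the peptide was not detected in
#' that sample.
#'
#' @param values numeric matrix, peptides in rows, samples in columns; no
#'   negative entries.
#' @param peptides data frame with columns `peptide_id` (unique),
#'   `protein_ids` (semicolon-separated accessions, at least one),
#'   `residue` (one of `"S"`, `"T"`, `"Y"`), `site_position` (positive
#'   integer, 1-based protein coordinate) and `sequence_window`
#'   (15-character window, phosphosite at the center, `_`-padded at
#'   protein ends).
#' @param samples character vector of sample identifiers; defaults to
#'   `colnames(values)`.
#' @return An object of class `phospho_matrix` with elements `values`,
#'   `peptides` and `samples`.
#' @export
phospho_matrix <- function(values, peptides, samples = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) stop_validation("sample identifiers are required")
  samples <- as.character(samples)
  if (!is.data.frame(peptides))
    stop_validation("`peptides` must be a data frame")
  missing_cols <- setdiff(.PEPTIDE_COLS, names(peptides))
  if (length(missing_cols))
    stop_validation("peptide table is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  peptides <- as.data.frame(peptides)[, .PEPTIDE_COLS]
  peptides$peptide_id <- as.character(peptides$peptide_id)
  peptides$protein_ids <- as.character(peptides$protein_ids)
  peptides$residue <- as.character(peptides$residue)
  peptides$site_position <- as.integer(peptides$site_position)
  peptides$sequence_window <- as.character(peptides$sequence_window)

  if (nrow(peptides) != nrow(values))
    stop_validation("peptide table and value matrix disagree on row count")
  if (length(samples) != ncol(values))
    stop_validation("sample vector and value matrix disagree on column count")
  if (anyDuplicated(peptides$peptide_id))
    stop_validation("duplicate peptide_id: ",
                    peptides$peptide_id[anyDuplicated(peptides$peptide_id)])
  if (anyDuplicated(samples))
    stop_validation("duplicate sample identifiers")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop_validation("negative intensity at row ", neg[1, 1],
                    " (peptide ", peptides$peptide_id[neg[1, 1]], ")")
  if (anyNA(values))
    stop_validation("NA intensities are not allowed; encode missing as 0")
  bad_res <- !peptides$residue %in% c("S", "T", "Y")
  if (any(bad_res))
    stop_validation("residue must be S, T or Y (peptide ",
                    peptides$peptide_id[which(bad_res)[1]], ")")
  if (any(is.na(peptides$site_position) | peptides$site_position < 1L))
    stop_validation("site_position must be a positive integer")
  bad_win <- nchar(peptides$sequence_window) != .WINDOW_WIDTH
  if (any(bad_win))
    stop_validation("sequence_window must be exactly ", .WINDOW_WIDTH,
                    " characters (peptide ",
                    peptides$peptide_id[which(bad_win)[1]], ")")
  centers <- substr(peptides$sequence_window, .WINDOW_CENTER, .WINDOW_CENTER)
  bad_center <- centers != peptides$residue
  if (any(bad_center))
    stop_validation("sequence_window center must equal the phosphoacceptor ",
                    "residue (peptide ",
                    peptides$peptide_id[which(bad_center)[1]], ")")
  if (any(!nzchar(peptides$protein_ids)))
    stop_validation("every peptide needs at least one protein accession")

  dimnames(values) <- list(peptides$peptide_id, samples)
  structure(list(values = values, peptides = peptides, samples = samples),
            class = "phospho_matrix")
}

#' @export
dim.phospho_matrix <- function(x) dim(x$values)

#' @export
print.phospho_matrix <- function(x, ...) {
  cat("Phosphopeptide intensity matrix:", nrow(x$values), "peptides x",
      ncol(x$values), "samples\n")
  det <- mean(x$values > 0)
  cat(sprintf("  detected cells: %.1f%%; residues: %s\n", 100 * det,
              paste(names(table(x$peptides$residue)),
                    table(x$peptides$residue), sep = "=", collapse = " ")))
  invisible(x)
}

# Restrict a phospho_matrix to a subset of samples (order respected).
subset_samples <- function(mat, keep) {
  stopifnot(inherits(mat, "phospho_matrix"))
  idx <- match(keep, mat$samples)
  if (anyNA(idx)) stop_validation("unknown sample(s): ",
                                  paste(keep[is.na(idx)], collapse = ", "))
  phospho_matrix(mat$values[, idx, drop = FALSE], mat$peptides,
                 mat$samples[idx])
}

#' Read a phosphopeptide intensity table
#'
#' Reads a delimited peptide-by-sample table. The first five columns must be
#' `peptide_id`, `protein_ids`, `residue`, `site_position` and
#' `sequence_window`; every remaining column is a sample. Empty intensity
#' cells are read as 0 ("not detected").
#'
#' @param path path to the table.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A [phospho_matrix()].
#' @export
read_intensity_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  missing_cols <- setdiff(.PEPTIDE_COLS, names(df))
  if (length(missing_cols))
    stop_validation("malformed header: missing column(s) ",
                    paste(missing_cols, collapse = ", "))
  sample_cols <- setdiff(names(df), .PEPTIDE_COLS)
  if (!length(sample_cols))
    stop_validation("no sample columns found")
  vals <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(vals) <- "double"
  vals[is.na(vals)] <- 0
  phospho_matrix(vals, df[, .PEPTIDE_COLS], sample_cols)
}

#' Read a sample annotation table
#'
#' @param path TSV with columns `sample_id`, `arm`
#'   (`standard`/`experimental`/`unknown`), `response`
#'   (`responder`/`nonresponder`) and optionally `site`.
#' @return Data frame of validated annotations.
#' @export
read_sample_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotations(df)
}

validate_annotations <- function(df) {
  need <- c("sample_id", "arm", "response")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop_validation("annotation table is missing column(s): ",
                    paste(missing_cols, collapse = ", "))
  if (!"site" %in% names(df)) df$site <- NA_character_
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop_validation("duplicate sample_id in annotations")
  if (!all(df$arm %in% c("standard", "experimental", "unknown")))
    stop_validation("arm must be standard, experimental or unknown")
  if (!all(df$response %in% c("responder", "nonresponder")))
    stop_validation("response must be responder or nonresponder")
  df[, c("sample_id", "arm", "response", "site")]
}

#' Align an intensity matrix with its sample annotations
#'
#' Restricts both inputs to their common samples, synchronizes ordering and
#' reports dropped identifiers. Requires at least two samples per response
#' group after alignment, the minimum any group comparison needs.
#'
#' @param matrix a [phospho_matrix()].
#' @param annotations annotation data frame (see
#'   [read_sample_annotations()]).
#' @return List with elements `matrix` and `annotations`, aligned.
#' @export
align_annotations <- function(matrix, annotations) {
  annotations <- validate_annotations(annotations)
  common <- intersect(matrix$samples, annotations$sample_id)
  dropped_m <- setdiff(matrix$samples, common)
  dropped_a <- setdiff(annotations$sample_id, common)
  if (length(dropped_m))
    message("dropping unannotated sample(s): ",
            paste(dropped_m, collapse = ", "))
  if (length(dropped_a))
    message("dropping annotation(s) without intensities: ",
            paste(dropped_a, collapse = ", "))
  ann <- annotations[match(common, annotations$sample_id), , drop = FALSE]
  counts <- table(factor(ann$response,
                         levels = c("responder", "nonresponder")))
  if (any(counts < 2L))
    stop("insufficient data: need >= 2 samples per response group, got ",
         counts[["responder"]], " responder(s) and ",
         counts[["nonresponder"]], " nonresponder(s)")
  list(matrix = subset_samples(matrix, common), annotations = ann)
}

#' Write a result table as TSV
#'
#' Writes any stage's result records with a stable column order and
#' full-precision numbers, so a re-read reproduces values to at least 12
#' significant digits.
#'
#' @param records a data frame, or a list of homogeneous records (lists
#'   sharing identical field names).
#' @param path destination path.
#' @return Invisibly, the written data frame.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!is.list(records))
      stop_validation("`records` must be a data frame or list of records")
    if (length(records)) {
      nm <- lapply(records, names)
      if (!all(vapply(nm, identical, logical(1), nm[[1]])))
        stop_validation("heterogeneous records: field names differ")
      records <- do.call(rbind,
                         lapply(records, function(r) as.data.frame(r)))
    } else {
      records <- data.frame()
    }
  }
  df <- as.data.frame(records)
  out <- df
  num <- vapply(out, is.numeric, logical(1)) & !vapply(out, is.integer,
                                                       logical(1))
  for (j in which(num)) out[[j]] <- format(out[[j]], digits = 17,
                                           scientific = FALSE, trim = TRUE)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write results table to ", path, ": ",
                        conditionMessage(ok))
  invisible(df)
}
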