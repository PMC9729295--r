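# Quantitative pull-down (AP-MS) interactor enrichment: zero -> 1
# substitution, per-replicate median-of-ratio normalization, bait/IgG
# scatter coordinates, candidate filtering and cross-cell-line fold
# changes.
#
# Bait pull-downs of true interactors sit orders of magnitude above the
# IgG isotype control (or are entirely absent from it); the 0 -> 1 psm
# substitution keeps ratios computable while preserving the "negligible
# abundance" meaning of a non-detection.

#' Construct a pull-down intensity table
#'
#' @param proteins character vector of protein identifiers (unique).
#' @param bait,igg numeric matrices (proteins x replicates) of nonnegative
#'   bait and IgG-control intensities; 0 means not detected.
#' @param cell_line,bait_name descriptive labels.
#' @return Object of class `pulldown_table`. The as-measured matrices are
#'   kept internally (`bait_obs`, `igg_obs`) so detection flags and psm
#'   floors always refer to the original data even after substitution and
#'   normalization.
#' @export
pulldown_table <- function(proteins, bait, igg, cell_line = "",
                           bait_name = "") {
  bait <- as.matrix(bait); igg <- as.matrix(igg)
  storage.mode(bait) <- "double"; storage.mode(igg) <- "double"
  proteins <- as.character(proteins)
  if (anyDuplicated(proteins)) stop_validation("duplicate protein ids")
  if (nrow(bait) != length(proteins) || nrow(igg) != length(proteins))
    stop_validation("matrix rows must match the protein vector")
  if (ncol(bait) < 1L || ncol(bait) != ncol(igg))
    stop_validation("bait and IgG need the same number (>= 1) of replicates")
  if (any(bait < 0) || any(igg < 0) || anyNA(bait) || anyNA(igg))
    stop_validation("intensities must be nonnegative; encode missing as 0")
  structure(list(proteins = proteins, bait = bait, igg = igg,
                 bait_obs = bait, igg_obs = igg,
                 cell_line = cell_line, bait_name = bait_name,
                 substituted = FALSE, normalized = FALSE),
            class = "pulldown_table")
}

#' @export
print.pulldown_table <- function(x, ...) {
  cat("Pull-down table: ", length(x$proteins), " proteins x ",
      ncol(x$bait), " replicate pair(s)", sep = "")
  if (nzchar(x$cell_line)) cat(" [", x$cell_line, ", bait ",
                               x$bait_name, "]", sep = "")
  cat("\n  zero-substituted:", x$substituted,
      "; median-ratio normalized:", x$normalized, "\n")
  invisible(x)
}

#' Read a pull-down table from TSV
#'
#' Expects columns `protein_id`, `cell_line`, `bait`, then
#' `bait_rep1..repK` and `igg_rep1..repK`.
#'
#' @param path path to the TSV.
#' @return A [pulldown_table()].
#' @export
read_pulldown_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  bait_cols <- grep("^bait_rep", names(df), value = TRUE)
  igg_cols <- grep("^igg_rep", names(df), value = TRUE)
  if (!"protein_id" %in% names(df) || !length(bait_cols) ||
      length(bait_cols) != length(igg_cols))
    stop_validation("pull-down table needs protein_id and matching ",
                    "bait_rep*/igg_rep* columns")
  vals <- function(cols) {
    m <- as.matrix(df[, cols, drop = FALSE]); m[is.na(m)] <- 0; m
  }
  pulldown_table(df$protein_id, vals(bait_cols), vals(igg_cols),
                 cell_line = if ("cell_line" %in% names(df))
                   df$cell_line[1] else "",
                 bait_name = if ("bait" %in% names(df)) df$bait[1] else "")
}

#' @export
as.data.frame.pulldown_table <- function(x, ...) {
  k <- ncol(x$bait)
  out <- data.frame(protein_id = x$proteins,
                    cell_line = x$cell_line, bait = x$bait_name)
  for (j in seq_len(k)) out[[paste0("bait_rep", j)]] <- x$bait[, j]
  for (j in seq_len(k)) out[[paste0("igg_rep", j)]] <- x$igg[, j]
  out
}

#' Zero-to-one substitution for pull-down intensities
#'
#' Every non-detected value (0) becomes 1; all other values are
#' unchanged. Idempotent. Detection flags computed later (e.g. "not
#' identified in IgG") always refer to the pre-substitution data.
#'
#' @param table a [pulldown_table()].
#' @return The table with zeros substituted and `substituted = TRUE`.
#' @export
zero_substitute <- function(table) {
  stopifnot(inherits(table, "pulldown_table"))
  table$bait[table$bait == 0] <- 1
  table$igg[table$igg == 0] <- 1
  table$substituted <- TRUE
  table
}

#' Median-of-ratio normalization per bait/control replicate pair
#'
#' For each replicate pair, every protein's bait/IgG ratio is divided by
#' the median ratio across proteins (implemented by scaling the bait
#' intensities), so the post-normalization median ratio is exactly 1.
#' Requires zero substitution first; with fewer than 3 proteins the step
#' is skipped with a warning.
#'
#' @param table a zero-substituted [pulldown_table()].
#' @return The normalized table.
#' @export
normalize_median_ratio <- function(table) {
  stopifnot(inherits(table, "pulldown_table"))
  if (!table$substituted)
    stop("apply zero_substitute() before normalization")
  if (length(table$proteins) < 3L) {
    warning("fewer than 3 proteins: median-ratio normalization skipped")
    return(table)
  }
  for (j in seq_len(ncol(table$bait))) {
    m <- stats::median(table$bait[, j] / table$igg[, j])
    table$bait[, j] <- table$bait[, j] / m
  }
  table$normalized <- TRUE
  table
}

#' Score proteins and apply the interactor candidate filter
#'
#' Coordinates per protein: `x = log2(mean bait / mean IgG)` and
#' `y = log10(mean bait + mean IgG)` over replicate-averaged normalized
#' intensities. A protein is a candidate when it shows evidence of
#' bait-specific binding -- `x` above `log2_threshold` or no detection in
#' any IgG replicate -- and clears the abundance floor: at least
#' `min_psm_bait` total in bait, or at least `min_psm_each_rep` in every
#' bait replicate (both evaluated on the as-measured intensities).
#'
#' @param table a substituted (and normally normalized)
#'   [pulldown_table()].
#' @param log2_threshold enrichment threshold (default 2).
#' @param min_psm_bait total-bait floor (default 3).
#' @param min_psm_each_rep per-replicate floor (default 1).
#' @return Data frame of class `pulldown_points`: `protein_id`, `x`, `y`,
#'   `avg_bait`, `avg_igg`, `igg_undetected`, `passes_abundance`,
#'   `is_candidate`.
#' @export
score_and_filter <- function(table, log2_threshold = 2, min_psm_bait = 3,
                             min_psm_each_rep = 1) {
  stopifnot(inherits(table, "pulldown_table"))
  if (!table$substituted)
    stop("apply zero_substitute() before scoring")
  avg_bait <- rowMeans(table$bait)
  avg_igg <- rowMeans(table$igg)
  igg_undetected <- rowSums(table$igg_obs > 0) == 0
  abundance <- rowSums(table$bait_obs) >= min_psm_bait |
    apply(table$bait_obs >= min_psm_each_rep, 1, all)
  x <- log2(avg_bait / avg_igg)
  y <- log10(avg_bait + avg_igg)
  out <- data.frame(protein_id = table$proteins, x = x, y = y,
                    avg_bait = avg_bait, avg_igg = avg_igg,
                    igg_undetected = igg_undetected,
                    passes_abundance = abundance,
                    is_candidate = (x > log2_threshold | igg_undetected) &
                      abundance,
                    row.names = NULL)
  class(out) <- c("pulldown_points", "data.frame")
  out
}

#' Cross-cell-line fold change of a protein's bait-bound intensity
#'
#' Ratio of the protein's replicate-averaged bait intensity in `table_b`
#' over `table_a`. A protein absent from one table contributes 1 (the
#' zero-substitution value) for that table; a protein present in neither
#' is an error.
#'
#' @param table_a,table_b substituted [pulldown_table()]s (typically
#'   normalized).
#' @param protein_id the protein to compare.
#' @return The fold change (table_b over table_a).
#' @export
compare_cell_lines <- function(table_a, table_b, protein_id) {
  stopifnot(inherits(table_a, "pulldown_table"),
            inherits(table_b, "pulldown_table"))
  ia <- match(protein_id, table_a$proteins)
  ib <- match(protein_id, table_b$proteins)
  if (is.na(ia) && is.na(ib))
    stop("protein not found in either table: ", protein_id)
  avg <- function(tbl, i) {
    if (is.na(i)) return(1)
    v <- tbl$bait[i, ]
    v[v == 0] <- 1
    mean(v)
  }
  avg(table_b, ib) / avg(table_a, ia)
}

#' Full pull-down screening stage
#'
#' Zero-substitutes, normalizes and scores a pull-down table in one call.
#'
#' @param table a [pulldown_table()] (raw).
#' @inheritParams score_and_filter
#' @return Object of class `pulldown_screen`: list with `points` (a
#'   `pulldown_points` data frame), the processed `table` and the
#'   thresholds used.
#' @export
pulldown_screen <- function(table, log2_threshold = 2, min_psm_bait = 3,
                            min_psm_each_rep = 1) {
  tbl <- normalize_median_ratio(zero_substitute(table))
  pts <- score_and_filter(tbl, log2_threshold, min_psm_bait,
                          min_psm_each_rep)
  structure(list(points = pts, table = tbl,
                 thresholds = c(log2_threshold = log2_threshold,
                                min_psm_bait = min_psm_bait,
                                min_psm_each_rep = min_psm_each_rep)),
            class = "pulldown_screen")
}

#' @export
print.pulldown_screen <- function(x, ...) {
  cat("Pull-down screen: ", nrow(x$points), " proteins, ",
      sum(x$points$is_candidate), " candidate interactor(s) at log2 > ",
      x$thresholds[["log2_threshold"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.pulldown_screen <- function(object, ...) {
  pts <- object$points
  cand <- pts[pts$is_candidate, , drop = FALSE]
  cat("Candidates:", nrow(cand), "of", nrow(pts), "\n")
  if (nrow(cand))
    print(utils::head(cand[order(-cand$x), c("protein_id", "x", "y",
                                             "igg_undetected")], 15),
          row.names = FALSE)
  invisible(cand)
}

#' @export
as.data.frame.pulldown_screen <- function(x, ...) x$points

#' Ratio-intensity scatter of a pull-down screen
#'
#' @param x a `pulldown_screen` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pulldown_screen <- function(x, ...) {
  pts <- x$points
  graphics::plot(pts$x, pts$y,
                 col = ifelse(pts$is_candidate, "firebrick", "grey50"),
                 pch = 16, cex = 0.7,
                 xlab = "log2 mean bait / mean IgG",
                 ylab = "log10 (mean bait + mean IgG)", ...)
  graphics::abline(v = x$thresholds[["log2_threshold"]], lty = 2,
                   col = "grey60")
  invisible(x)
}
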