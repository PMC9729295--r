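# Phospho-motif patterns and kinase-set construction.
#
# A motif pattern is a set of positional residue constraints around the
# phosphosite, in the style of linear kinase-recognition motifs
# (e.g. `R-X-X-pS/pT`: arginine three residues N-terminal of a phospho-Ser
# or phospho-Thr). Patterns are matched against the 15-residue sequence
# window of each phosphopeptide; `_` padding (protein termini) never
# satisfies a constraint.

#' Parse a linear phospho-motif pattern string
#'
#' Pattern syntax: dash-separated positions; `pS`, `pT`, `pY` (combinable
#' as `pS/pT`) mark the phosphoacceptor (offset 0); `X` is a wildcard;
#' a single letter requires that residue; a bracket group like `[RK]`
#' allows any listed residue; a slash group `S/T` is equivalent to `[ST]`.
#'
#' @param pattern pattern string, e.g. `"R-X-X-pS/pT"`.
#' @param kinase_id optional kinase identifier attached to the result.
#' @return An object of class `motif_pattern`: list with `kinase_id`,
#'   integer `offsets` (relative to the phosphosite) and a list `allowed`
#'   of residue sets, the offset-0 entry being the allowed
#'   phosphoacceptors.
#' @export
parse_motif <- function(pattern, kinase_id = NA_character_) {
  stopifnot(is_string(pattern))
  tokens <- strsplit(pattern, "-", fixed = TRUE)[[1]]
  if (!length(tokens)) stop_validation("empty motif pattern")
  is_center <- grepl("^p[STY](/p[STY])*$", tokens)
  if (sum(is_center) != 1L)
    stop_validation("pattern must contain exactly one phosphoacceptor ",
                    "token (pS, pT, pY or a /-combination): ", pattern)
  center_idx <- which(is_center)
  offsets <- integer(0)
  allowed <- list()
  for (i in seq_along(tokens)) {
    off <- i - center_idx
    tok <- tokens[i]
    if (i == center_idx) {
      res <- sub("^p", "", strsplit(tok, "/", fixed = TRUE)[[1]])
      res <- sub("^p", "", res)
    } else if (tok == "X") {
      next
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      res <- strsplit(gsub("\\[|\\]", "", tok), "")[[1]]
    } else if (grepl("^[A-Z](/[A-Z])*$", tok)) {
      res <- strsplit(tok, "/", fixed = TRUE)[[1]]
    } else {
      stop_validation("cannot parse motif token '", tok, "' in: ", pattern)
    }
    if (abs(off) > 7L)
      stop_validation("motif offset ", off, " outside the 15-residue window")
    offsets <- c(offsets, off)
    allowed <- c(allowed, list(unique(res)))
  }
  structure(list(kinase_id = kinase_id, pattern = pattern,
                 offsets = offsets, allowed = allowed),
            class = "motif_pattern")
}

#' Read a kinase motif library
#'
#' @param path TSV with columns `kinase_id` and `pattern`
#'   (see [parse_motif()] for the pattern syntax). A kinase may own
#'   several patterns (one row each).
#' @return List of `motif_pattern` objects, class `motif_library`.
#' @export
read_motif_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("kinase_id", "pattern")
  if (!all(need %in% names(df)))
    stop_validation("motif library needs columns kinase_id and pattern")
  as_motif_library(Map(parse_motif, df$pattern, df$kinase_id))
}

as_motif_library <- function(patterns) {
  if (inherits(patterns, "motif_library")) return(patterns)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  stopifnot(all(vapply(patterns, inherits, logical(1), "motif_pattern")))
  structure(unname(patterns), class = "motif_library")
}

#' Write a motif library as TSV
#' @param library a `motif_library` (or list of `motif_pattern`).
#' @param path destination path.
#' @export
write_motif_library <- function(library, path) {
  library <- as_motif_library(library)
  df <- data.frame(kinase_id = vapply(library, `[[`, "", "kinase_id"),
                   pattern = vapply(library, `[[`, "", "pattern"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}

#' Match a phosphosite sequence window against motif patterns
#'
#' A kinase is returned iff at least one of its patterns has every
#' positional constraint satisfied. The `_` padding character at protein
#' termini never matches.
#'
#' @param window 15-character sequence window, phosphosite at the center.
#' @param residue phosphoacceptor residue, `"S"`, `"T"` or `"Y"`.
#' @param patterns a `motif_library` or list of `motif_pattern`.
#' @return Character vector of matching kinase identifiers (unique).
#' @export
match_motifs <- function(window, residue, patterns) {
  if (!is_string(window) || nchar(window) != .WINDOW_WIDTH)
    stop_validation("sequence window must be a single ", .WINDOW_WIDTH,
                    "-character string")
  patterns <- as_motif_library(patterns)
  chars <- strsplit(window, "")[[1]]
  hits <- vapply(patterns, function(p) {
    for (k in seq_along(p$offsets)) {
      off <- p$offsets[k]
      ch <- if (off == 0L) residue else chars[.WINDOW_CENTER + off]
      if (ch == "_" || !(ch %in% p$allowed[[k]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  unique(vapply(patterns[hits], `[[`, "", "kinase_id"))
}

# Vectorized membership: peptides x patterns, then collapsed per kinase.
match_motifs_matrix <- function(peptides, patterns) {
  patterns <- as_motif_library(patterns)
  n <- nrow(peptides)
  wm <- matrix(unlist(strsplit(peptides$sequence_window, ""), use.names = FALSE),
               nrow = n, byrow = TRUE)
  out <- matrix(FALSE, n, length(patterns))
  for (j in seq_along(patterns)) {
    p <- patterns[[j]]
    ok <- rep(TRUE, n)
    for (k in seq_along(p$offsets)) {
      off <- p$offsets[k]
      ch <- if (off == 0L) peptides$residue else wm[, .WINDOW_CENTER + off]
      ok <- ok & ch %in% p$allowed[[k]] & ch != "_"
    }
    out[, j] <- ok
  }
  out
}

#' Build kinase substrate sets from motif matches
#'
#' Assigns every peptide of the matrix to each kinase with a matching
#' motif, then applies the enrichment size gate: only sets with more than
#' `min_size - 1` and fewer than `max_size + 1` members are kept
#' (defaults keep sizes 6..999, i.e. >5 and <1000).
#'
#' @param matrix a [phospho_matrix()].
#' @param patterns a `motif_library`.
#' @param min_size smallest admissible set size (default 6).
#' @param max_size largest admissible set size (default 999).
#' @return Named list of character vectors (peptide ids per kinase),
#'   class `kinase_sets`, with attribute `excluded` naming filtered
#'   kinases and their sizes.
#' @export
build_kinase_sets <- function(matrix, patterns, min_size = 6L,
                              max_size = 999L) {
  patterns <- as_motif_library(patterns)
  if (!length(patterns)) stop_validation("motif library is empty")
  mm <- match_motifs_matrix(matrix$peptides, patterns)
  kin <- vapply(patterns, `[[`, "", "kinase_id")
  sets <- lapply(split(seq_along(patterns), kin), function(cols) {
    matrix$peptides$peptide_id[rowSums(mm[, cols, drop = FALSE]) > 0]
  })
  sets <- sets[lengths(sets) > 0]
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  excluded <- data.frame(kinase_id = names(sets)[!keep],
                         size = unname(sizes[!keep]))
  if (nrow(excluded))
    message("excluding ", nrow(excluded),
            " kinase set(s) outside the size gate [", min_size, ", ",
            max_size, "]")
  if (!any(keep))
    warning("no kinase set survives the size gate")
  structure(sets[keep], class = "kinase_sets", excluded = excluded)
}
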