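# Responder-vs-nonresponder differential phosphopeptide analysis:
# per-peptide medians with zero -> 1 substituted log2 fold changes,
# Monte-Carlo Mann-Whitney-Wilcoxon permutation p-values,
# Benjamini-Hochberg FDR control, and volcano hit classification.
#
# Zeros (not-detected) are retained as observed values inside the rank
# test; the zero -> 1 substitution applies only to the median ratio, where
# it exists purely to make the fold change computable when one group never
# detects the peptide. A spectral-intensity change of 1 is negligible
# against the 2^10..2^20 range of detected intensities, so the substituted
# ratio keeps its biological meaning.

#' Normality gate for the pooled intensity distribution
#'
#' Shapiro-Wilk test deciding between the parametric and nonparametric
#' analysis branches. The pipeline applies this once to the pooled
#' intensity distribution; phosphoproteomic intensity data are heavy-tailed
#' and routinely fail the gate, selecting the Mann-Whitney branch.
#'
#' @param values numeric vector, 3 to 5000 observations.
#' @param alpha rejection level (default 0.05).
#' @return List with `branch` (`"parametric"` or `"nonparametric"`),
#'   `p_value` and `statistic`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- as.numeric(values)
  values <- values[!is.na(values)]
  if (length(values) < 3L)
    stop("insufficient data: normality gate needs at least 3 values")
  if (length(values) > 5000L)
    stop("normality gate accepts at most 5000 values; subsample first")
  if (diff(range(values)) == 0)
    stop("insufficient variation: all values identical")
  sw <- stats::shapiro.test(values)
  list(branch = if (sw$p.value < alpha) "nonparametric" else "parametric",
       p_value = sw$p.value, statistic = unname(sw$statistic))
}

#' Group medians, zero-substituted log2 fold change and cloud label
#'
#' Medians are computed on the raw intensities (zeros are observations).
#' For the ratio only, a group median of 0 is replaced by 1, which places
#' peptides undetectable in one group on the characteristic lateral
#' volcano clouds at `x = +/- log2(median of the detecting group)`.
#'
#' @param row numeric vector of intensities for one peptide.
#' @param is_responder logical vector, same length, `TRUE` for responders.
#' @return List with `median_responder`, `median_nonresponder`, `log2_fc`
#'   and `cloud` (`"shared"`, `"exclusive_responder"` or
#'   `"exclusive_nonresponder"`).
#' @export
median_log2_fc <- function(row, is_responder) {
  stopifnot(length(row) == length(is_responder))
  if (!any(is_responder) || all(is_responder))
    stop("both groups must be nonempty")
  m_r <- stats::median(row[is_responder])
  m_n <- stats::median(row[!is_responder])
  cloud <- if (m_r == 0 && m_n > 0) "exclusive_nonresponder"
           else if (m_n == 0 && m_r > 0) "exclusive_responder"
           else "shared"
  log2_fc <- log2(max(m_r, if (m_r == 0) 1 else m_r) /
                  max(m_n, if (m_n == 0) 1 else m_n))
  list(median_responder = m_r, median_nonresponder = m_n,
       log2_fc = log2_fc, cloud = cloud)
}

#' Monte-Carlo Mann-Whitney-Wilcoxon permutation test
#'
#' Two-sided permutation test on the rank-sum statistic with midrank ties.
#' Group labels are shuffled by a seeded RNG; the p-value uses the add-one
#' estimator `(1 + #extreme) / (n_perm + 1)`, which never returns 0 and at
#' the default 100,000 permutations resolves p-values to five decimal
#' places.
#'
#' @param x,y numeric vectors for the two groups (each of length >= 2).
#' @param n_perm number of label permutations (default 100000).
#' @param seed integer seed for the permutation stream.
#' @return The two-sided Monte-Carlo p-value in `(0, 1]`.
#' @seealso [mww_exact_p()] for the exhaustive-enumeration analogue.
#' @export
mww_permutation_test <- function(x, y, n_perm = 100000L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  e_w <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - e_w)
  count <- with_seed(seed, {
    total <- 0L
    chunk <- 20000L
    done <- 0L
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      idx <- vapply(seq_len(b), function(i) sample.int(N, n1),
                    integer(n1))
      w <- colSums(matrix(r[idx], nrow = n1))
      total <- total + sum(abs(w - e_w) >= obs - 1e-9)
      done <- done + b
    }
    total
  })
  (1 + count) / (n_perm + 1)
}

#' Exact Mann-Whitney-Wilcoxon permutation p-value
#'
#' Exhaustively enumerates all `choose(n1+n2, n1)` relabelings and returns
#' the exact two-sided permutation p-value of the rank-sum statistic
#' (midrank ties). Intended for small groups; the enumeration size is
#' capped at 2e6.
#'
#' @inheritParams mww_permutation_test
#' @return Exact two-sided p-value in `(0, 1]`.
#' @export
mww_exact_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); N <- n1 + length(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  n_comb <- choose(N, n1)
  if (n_comb > 2e6) stop("too many relabelings for exhaustive enumeration")
  r <- rank(c(x, y))
  e_w <- n1 * (N + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - e_w)
  combs <- utils::combn(N, n1)
  w <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(w - e_w) >= obs - 1e-9)
}

# Vectorized Monte-Carlo MWW across the rows of an intensity matrix.
# One shared, seeded permutation stream drives all peptides (the
# permutation set is ancillary to the per-peptide data, so marginal
# p-values are unaffected); the statistic is computed for all rows and
# permutations via a rank-matrix product.
mww_perm_matrix <- function(values, is_g1, n_perm, seed, chunk = 4000L) {
  n1 <- sum(is_g1); N <- length(is_g1)
  rk <- t(apply(values, 1, rank))
  e_w <- n1 * (N + 1) / 2
  obs <- abs(rowSums(rk[, is_g1, drop = FALSE]) - e_w)
  count <- numeric(nrow(values))
  with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      b <- as.integer(min(chunk, n_perm - done))
      g <- matrix(0, N, b)
      for (j in seq_len(b)) g[sample.int(N, n1), j] <- 1
      w <- rk %*% g
      count <- count + rowSums(abs(w - e_w) >= obs - 1e-9)
      done <- done + b
    }
  })
  (1 + count) / (n_perm + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param p_values numeric vector of raw p-values in `(0, 1]`.
#' @return Vector of q-values in `(0, 1]`.
#' @export
benjamini_hochberg <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0) || any(p > 1))
    stop_validation("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify volcano hits
#'
#' Applies the screening thresholds with strict inequalities: a peptide is
#' a hit when `|log2_fc|` exceeds `fc_threshold_log2` (default 4, i.e.
#' 16-fold), the raw permutation p-value is below `p_threshold` (default
#' `10^-2.5`), and the BH q-value is below `fdr_threshold` (default 0.25).
#' Volcano coordinates (`x = log2_fc`, `y = -log10(p_raw)`) are added.
#'
#' @param results data frame with columns `log2_fc`, `p_raw` and `q_bh`.
#' @param fc_threshold_log2,p_threshold,fdr_threshold hit thresholds.
#' @return The data frame with `volcano_x`, `volcano_y` and `is_hit` added.
#' @export
classify_volcano_hits <- function(results, fc_threshold_log2 = 4,
                                  p_threshold = 10^-2.5,
                                  fdr_threshold = 0.25) {
  stopifnot(all(c("log2_fc", "p_raw", "q_bh") %in% names(results)))
  results$volcano_x <- results$log2_fc
  results$volcano_y <- -log10(results$p_raw)
  results$is_hit <- abs(results$log2_fc) > fc_threshold_log2 &
    results$p_raw < p_threshold & results$q_bh < fdr_threshold
  results
}

#' Differential phosphopeptide analysis between response groups
#'
#' Runs the full per-peptide comparison of responders (pathologic complete
#' response) versus nonresponders: optional arm filtering, a single
#' Shapiro-Wilk gate on the pooled intensity distribution, per-peptide
#' medians and zero-substituted log2 fold changes, Monte-Carlo
#' Mann-Whitney-Wilcoxon permutation p-values, Benjamini-Hochberg
#' q-values, and volcano hit classification.
#'
#' @param matrix a [phospho_matrix()].
#' @param annotations sample annotation data frame.
#' @param arm `"all"` (default), `"standard"` or `"experimental"`; the
#'   per-arm analyses are the same code path under a sample filter.
#' @param n_perm Monte-Carlo permutations per peptide (default 100000).
#' @param seed integer seed; the permutation stream is the
#'   `"diff-permutations"` substream of this seed.
#' @param fc_threshold_log2,p_threshold,fdr_threshold hit thresholds, see
#'   [classify_volcano_hits()].
#' @param normality_alpha level of the Shapiro-Wilk gate.
#' @return Object of class `phospho_diff`: list with `results` (one row
#'   per peptide), `gate`, group sizes and the parameters used.
#' @export
phospho_diff <- function(matrix, annotations, arm = c("all", "standard",
                                                      "experimental"),
                         n_perm = 100000L, seed = 1L,
                         fc_threshold_log2 = 4, p_threshold = 10^-2.5,
                         fdr_threshold = 0.25, normality_alpha = 0.05) {
  arm <- match.arg(arm)
  al <- align_annotations(matrix, annotations)
  ann <- al$annotations
  if (arm != "all") {
    keep <- ann$arm == arm
    ann <- ann[keep, , drop = FALSE]
    if (sum(ann$response == "responder") < 2L ||
        sum(ann$response == "nonresponder") < 2L)
      stop("insufficient data: need >= 2 samples per response group in arm ",
           arm)
    al$matrix <- subset_samples(al$matrix, ann$sample_id)
  }
  mat <- al$matrix
  is_r <- ann$response == "responder"

  pooled <- as.vector(mat$values)
  if (length(pooled) > 5000L)
    pooled <- with_seed(substream_seed(seed, "diff-gate"),
                        sample(pooled, 5000L))
  gate <- normality_gate(pooled, alpha = normality_alpha)

  med <- t(apply(mat$values, 1, function(row) {
    f <- median_log2_fc(row, is_r)
    c(f$median_responder, f$median_nonresponder, f$log2_fc)
  }))
  cloud <- ifelse(med[, 1] == 0 & med[, 2] > 0, "exclusive_nonresponder",
                  ifelse(med[, 2] == 0 & med[, 1] > 0,
                         "exclusive_responder", "shared"))

  p_raw <- mww_perm_matrix(mat$values, is_r, n_perm = n_perm,
                           seed = substream_seed(seed, "diff-permutations"))
  res <- data.frame(peptide_id = mat$peptides$peptide_id,
                    median_responder = med[, 1],
                    median_nonresponder = med[, 2],
                    log2_fc = med[, 3],
                    p_raw = p_raw,
                    q_bh = benjamini_hochberg(p_raw),
                    cloud = cloud,
                    row.names = NULL)
  res <- classify_volcano_hits(res, fc_threshold_log2, p_threshold,
                               fdr_threshold)
  structure(list(results = res, gate = gate,
                 n_responders = sum(is_r), n_nonresponders = sum(!is_r),
                 arm = arm, n_perm = n_perm, seed = seed,
                 thresholds = c(fc_threshold_log2 = fc_threshold_log2,
                                p_threshold = p_threshold,
                                fdr_threshold = fdr_threshold)),
            class = "phospho_diff")
}

#' @export
print.phospho_diff <- function(x, ...) {
  cat("Differential phosphopeptide analysis (", x$arm, " arm)\n", sep = "")
  cat("  ", nrow(x$results), " peptides; ", x$n_responders,
      " responders vs ", x$n_nonresponders, " nonresponders\n", sep = "")
  cat("  normality gate: ", x$gate$branch,
      sprintf(" (Shapiro-Wilk p = %.3g)\n", x$gate$p_value), sep = "")
  cat("  hits: ", sum(x$results$is_hit), " (|log2FC| > ",
      x$thresholds[["fc_threshold_log2"]], ", p < ",
      format(x$thresholds[["p_threshold"]], digits = 3), ", q < ",
      x$thresholds[["fdr_threshold"]], ")\n", sep = "")
  invisible(x)
}

#' @export
summary.phospho_diff <- function(object, ...) {
  res <- object$results
  out <- list(n_peptides = nrow(res),
              clouds = table(res$cloud),
              n_hits = sum(res$is_hit),
              hits = res[res$is_hit, , drop = FALSE],
              min_p = min(res$p_raw))
  class(out) <- "summary.phospho_diff"
  out
}

#' @export
print.summary.phospho_diff <- function(x, ...) {
  cat("Peptides tested:", x$n_peptides, "\n")
  cat("Cloud membership:\n")
  print(x$clouds)
  cat("Smallest raw p-value:", format(x$min_p, digits = 4), "\n")
  cat("Hits:", x$n_hits, "\n")
  if (nrow(x$hits)) {
    ord <- order(x$hits$p_raw)
    print(utils::head(x$hits[ord, c("peptide_id", "log2_fc", "p_raw",
                                    "q_bh", "cloud")], 10))
  }
  invisible(x)
}

#' @export
as.data.frame.phospho_diff <- function(x, ...) x$results

#' Volcano plot of a differential analysis
#'
#' @param x a `phospho_diff` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.phospho_diff <- function(x, ...) {
  res <- x$results
  col <- ifelse(res$is_hit, "firebrick",
                ifelse(res$cloud == "shared", "grey40", "steelblue"))
  graphics::plot(res$volcano_x, res$volcano_y, col = col, pch = 16,
                 cex = 0.6, xlab = "log2 fold change (responders / nonresponders)",
                 ylab = "-log10 raw p", ...)
  graphics::abline(v = c(-1, 1) * x$thresholds[["fc_threshold_log2"]],
                   lty = 2, col = "grey60")
  graphics::abline(h = -log10(x$thresholds[["p_threshold"]]), lty = 2,
                   col = "grey60")
  invisible(x)
}
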