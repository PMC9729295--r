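# Immunohistochemistry biomarker confirmation: H-scores, upper-quartile
# dichotomization, pCR association with chi-square and Bonferroni control,
# combined-marker pCR rates and pairwise marker correlations.

#' IHC H-score
#'
#' `((%high * 3) + (%medium * 2) + (%low * 1)) / 100`, yielding a staining
#' summary in `[0, 3]`.
#'
#' @param pct_high,pct_medium,pct_low staining area percentages in
#'   `[0, 100]`, summing to at most 100 (vectorized).
#' @return Numeric H-score(s) in `[0, 3]`.
#' @export
h_score <- function(pct_high, pct_medium, pct_low) {
  v <- cbind(pct_high, pct_medium, pct_low)
  if (anyNA(v) || any(v < 0) || any(v > 100))
    stop_validation("area percentages must lie in [0, 100]")
  if (any(rowSums(v) > 100 + 1e-9))
    stop_validation("area percentages must sum to at most 100")
  as.numeric((pct_high * 3 + pct_medium * 2 + pct_low * 1) / 100)
}

#' Upper-quartile dichotomization of H-scores
#'
#' Patients with an H-score strictly above the cohort's 75th percentile
#' (linear-interpolation quantile) are `High`; scores at or below the
#' cutoff are `Low`.
#'
#' @param h_scores numeric vector, at least 4 values.
#' @return Character vector of `"High"`/`"Low"`, with the cutoff attached
#'   as attribute `cutoff`.
#' @export
quartile_categorize <- function(h_scores) {
  h <- as.numeric(h_scores)
  if (length(h) < 4L || anyNA(h))
    stop("insufficient data: need >= 4 complete H-scores")
  cutoff <- unname(stats::quantile(h, 0.75, type = 7))
  structure(ifelse(h > cutoff, "High", "Low"), cutoff = cutoff)
}

#' Association between upper-quartile marker status and pCR
#'
#' Builds the 2x2 table of High/Low marker status against pathologic
#' complete response and reports both effect measures (the usual
#' "fold higher chance" phrasing is ambiguous between them): the risk
#' ratio of pCR
#' proportions and the cross-product odds ratio (the exponent of the
#' univariate logistic coefficient for a binary covariate). Significance
#' uses the Pearson chi-square without continuity correction and a
#' Bonferroni adjustment over `m_comparisons`; the adjusted p is called
#' `significant` below 0.01, `borderline` between 0.01 and 0.1, `ns`
#' otherwise.
#'
#' @param records data frame for one marker with columns `h_score` (or the
#'   three `pct_*` columns) and logical `pcr`; optionally `patient_id`.
#' @param m_comparisons Bonferroni denominator (default 5, one per marker
#'   in a confirmation set).
#' @return One-row data frame of class `marker_association`.
#' @export
association_test <- function(records, m_comparisons = 5L) {
  records <- as.data.frame(records)
  if (!"h_score" %in% names(records))
    records$h_score <- h_score(records$pct_high, records$pct_medium,
                               records$pct_low)
  stopifnot("pcr" %in% names(records))
  pcr <- as.logical(records$pcr)
  grp <- quartile_categorize(records$h_score)
  hi <- grp == "High"
  if (!any(hi) || all(hi))
    stop("both High and Low groups must be nonempty")
  n_q1 <- sum(hi); n_rest <- sum(!hi)
  pcr_q1 <- sum(pcr[hi]); pcr_rest <- sum(pcr[!hi])

  risk_ratio <- (pcr_q1 / n_q1) / (pcr_rest / n_rest)
  a <- pcr_q1; b <- n_q1 - pcr_q1; c <- pcr_rest; d <- n_rest - pcr_rest
  haldane <- any(c(a, b, c, d) == 0)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  odds_ratio <- (a * d) / (b * c)

  tab <- rbind(c(pcr_q1, n_q1 - pcr_q1), c(pcr_rest, n_rest - pcr_rest))
  if ((pcr_q1 / n_q1) == (pcr_rest / n_rest)) {
    chi2 <- 0; p_raw <- 1
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p_raw <- ct$p.value
  }
  p_bonf <- min(1, m_comparisons * p_raw)
  call <- if (p_bonf < 0.01) "significant"
          else if (p_bonf <= 0.1) "borderline" else "ns"
  out <- data.frame(marker = if ("marker" %in% names(records))
                      records$marker[1] else NA_character_,
                    n_q1 = n_q1, n_rest = n_rest,
                    pcr_q1 = pcr_q1, pcr_rest = pcr_rest,
                    cutoff = attr(grp, "cutoff"),
                    risk_ratio = risk_ratio, odds_ratio = odds_ratio,
                    haldane_corrected = haldane,
                    chi2_stat = chi2, p_raw = p_raw,
                    p_bonferroni = p_bonf, call = call,
                    row.names = NULL)
  class(out) <- c("marker_association", "data.frame")
  out
}

#' pCR rate of patients in the upper quartile of two markers jointly
#'
#' Identifies patients `High` on both markers, reports their pCR
#' proportion with the standard error of the proportion, and compares it
#' against all remaining patients with the Pearson chi-square.
#'
#' @param records long-format IHC data frame (`patient_id`, `marker`,
#'   `h_score` or `pct_*` columns, `pcr`) containing both markers.
#' @param marker_a,marker_b the two marker names.
#' @return List with `n_both_q1`, `pcr_rate_both_q1`, `se_proportion`,
#'   `n_rest`, `pcr_rate_rest`, `chi2_stat`, `p_value` and `status`
#'   (`"ok"`, `"empty_stratum"` or `"no_comparison_stratum"`).
#' @export
combined_marker_rate <- function(records, marker_a, marker_b) {
  records <- as.data.frame(records)
  if (!"h_score" %in% names(records))
    records$h_score <- h_score(records$pct_high, records$pct_medium,
                               records$pct_low)
  sub <- function(mk) {
    r <- records[records$marker == mk, , drop = FALSE]
    if (!nrow(r)) stop_validation("marker not present: ", mk)
    r
  }
  ra <- sub(marker_a); rb <- sub(marker_b)
  common <- intersect(ra$patient_id, rb$patient_id)
  if (!length(common))
    stop_validation("markers share no patients")
  ra <- ra[match(common, ra$patient_id), ]
  rb <- rb[match(common, rb$patient_id), ]
  both_hi <- quartile_categorize(ra$h_score) == "High" &
    quartile_categorize(rb$h_score) == "High"
  pcr <- as.logical(ra$pcr)

  n_both <- sum(both_hi)
  if (n_both == 0L)
    return(list(n_both_q1 = 0L, pcr_rate_both_q1 = NA_real_,
                se_proportion = NA_real_, n_rest = length(common),
                pcr_rate_rest = mean(pcr), chi2_stat = NA_real_,
                p_value = NA_real_, status = "empty_stratum"))
  rate <- mean(pcr[both_hi])
  se <- sqrt(rate * (1 - rate) / n_both)
  if (all(both_hi))
    return(list(n_both_q1 = n_both, pcr_rate_both_q1 = rate,
                se_proportion = se, n_rest = 0L,
                pcr_rate_rest = NA_real_, chi2_stat = NA_real_,
                p_value = NA_real_, status = "no_comparison_stratum"))
  tab <- rbind(c(sum(pcr[both_hi]), sum(!pcr[both_hi])),
               c(sum(pcr[!both_hi]), sum(!pcr[!both_hi])))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(n_both_q1 = n_both, pcr_rate_both_q1 = rate, se_proportion = se,
       n_rest = sum(!both_hi), pcr_rate_rest = mean(pcr[!both_hi]),
       chi2_stat = unname(ct$statistic), p_value = ct$p.value,
       status = "ok")
}

#' Pairwise Pearson correlation between two markers' H-scores
#'
#' @param x,y paired numeric H-score vectors, n >= 3.
#' @return List with `pearson_r` and `p_value` (two-sided t
#'   approximation).
#' @export
marker_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need paired vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value)
}

#' Screen several IHC markers for association with pCR
#'
#' Runs [association_test()] per marker (Bonferroni over the number of
#' markers by default, matching one confirmation set of comparisons).
#'
#' @param records long-format IHC data frame with columns `patient_id`,
#'   `marker`, `h_score` or `pct_*`, `pcr`.
#' @param markers marker names to screen (default: all present).
#' @param m_comparisons Bonferroni denominator (default: number of
#'   markers screened).
#' @return Object of class `ihc_screen`: data frame of one
#'   `marker_association` row per marker.
#' @export
ihc_screen <- function(records, markers = NULL, m_comparisons = NULL) {
  records <- as.data.frame(records)
  if (is.null(markers)) markers <- unique(records$marker)
  if (is.null(m_comparisons)) m_comparisons <- length(markers)
  rows <- lapply(markers, function(mk) {
    r <- records[records$marker == mk, , drop = FALSE]
    out <- association_test(r, m_comparisons = m_comparisons)
    out$marker <- mk
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ihc_screen", "data.frame")
  attr(out, "m_comparisons") <- m_comparisons
  out
}

#' @export
print.ihc_screen <- function(x, ...) {
  cat("IHC upper-quartile association screen (", nrow(x),
      " markers, Bonferroni m = ", attr(x, "m_comparisons"), ")\n",
      sep = "")
  df <- as.data.frame(x)
  df$risk_ratio <- round(df$risk_ratio, 2)
  df$odds_ratio <- round(df$odds_ratio, 2)
  print(df[, c("marker", "n_q1", "pcr_q1", "n_rest", "pcr_rest",
               "risk_ratio", "odds_ratio", "p_raw", "p_bonferroni",
               "call")], row.names = FALSE)
  invisible(x)
}

#' Bar plot of pCR rates by marker quartile group
#'
#' @param x an `ihc_screen` object.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.ihc_screen <- function(x, ...) {
  rates <- rbind(Q1 = x$pcr_q1 / x$n_q1, `Q2-4` = x$pcr_rest / x$n_rest)
  colnames(rates) <- x$marker
  graphics::barplot(rates, beside = TRUE, ylim = c(0, 1),
                    ylab = "pCR rate", legend.text = TRUE, ...)
  invisible(x)
}
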