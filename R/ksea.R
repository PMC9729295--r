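# Kinase-set enrichment analysis (KSEA): t-statistic ranking of
# phosphopeptides, classic (unweighted) Kolmogorov-Smirnov-style running-sum
# enrichment score, and phenotype-permutation NES / p / FDR.
#
# "Classic" scoring walks down the ranked list adding 1/n_hit at set
# members and subtracting 1/(N - n_hit) elsewhere; the enrichment score is
# the signed extreme of the running sum and depends only on the ordering,
# not on the magnitudes of the ranking scores. Internally the running sum
# is kept as an integer numerator over the common denominator
# n_hit * (N - n_hit), so scores are exact.

#' Rank peptides by the two-sample t statistic
#'
#' Pooled-variance two-sample t of responders minus nonresponders, by
#' default on `log2(intensity + 1)`. Peptides are ordered by descending
#' statistic; ties (including zero-variance peptides, which get t = 0)
#' are broken lexicographically by `peptide_id` for determinism.
#'
#' @param matrix a [phospho_matrix()].
#' @param is_responder logical vector over the matrix samples.
#' @param log_transform log2(x+1)-transform intensities first (default
#'   TRUE).
#' @return Data frame (`peptide_id`, `stat`) in ranking order, class
#'   `ranked_list`.
#' @export
rank_by_tstat <- function(matrix, is_responder, log_transform = TRUE) {
  if (sum(is_responder) < 2L || sum(!is_responder) < 2L)
    stop("each group needs at least 2 samples")
  v <- matrix$values
  if (log_transform) v <- log2(v + 1)
  t_stat <- row_tstats(v, is_responder)
  ord <- order(-t_stat, matrix$peptides$peptide_id)
  structure(data.frame(peptide_id = matrix$peptides$peptide_id[ord],
                       stat = t_stat[ord], row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

# Pooled-variance t for every row; zero-variance rows get 0.
row_tstats <- function(v, g1) {
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(v[, g1, drop = FALSE])
  m2 <- rowMeans(v[, !g1, drop = FALSE])
  ss1 <- rowSums((v[, g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((v[, !g1, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, (m1 - m2) / se, 0)
  t_stat
}

# Pooled t for all rows and B group-membership columns at once.
# g is an n_samples x B 0/1 matrix; each column flags the "responder"
# relabeling. Returns a rows x B matrix of t statistics.
row_tstats_perm <- function(v, g) {
  n <- ncol(v)
  n1 <- colSums(g)
  stopifnot(all(n1 == n1[1]))
  n1 <- n1[1]; n2 <- n - n1
  s1 <- v %*% g
  q1 <- (v * v) %*% g
  tot <- rowSums(v); tot2 <- rowSums(v * v)
  s2 <- tot - s1
  q2 <- tot2 - q1
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- q1 - n1 * m1 * m1
  ss2 <- q2 - n2 * m2 * m2
  sp2 <- (ss1 + ss2) / (n - 2)
  sp2[sp2 < 1e-12] <- 0
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  out <- (m1 - m2) / se
  out[se == 0] <- 0
  out
}

#' Classic running-sum enrichment score
#'
#' Unweighted enrichment statistic over a ranked list: the running sum
#' gains `1/n_hit` at each set member and loses `1/(N - n_hit)` at each
#' non-member; the score is the extreme of largest magnitude (signed,
#' positive preferred on an exact tie). Lies in `[-1, 1]`.
#'
#' @param ranked ranked peptide identifiers: a character vector in ranking
#'   order, or a `ranked_list` from [rank_by_tstat()].
#' @param set_members character vector of member peptide ids; must overlap
#'   the ranked list but not cover it entirely.
#' @return The enrichment score.
#' @export
enrichment_score_classic <- function(ranked, set_members) {
  if (inherits(ranked, "ranked_list") || is.data.frame(ranked))
    ranked <- ranked$peptide_id
  ranked <- as.character(ranked)
  pos <- which(ranked %in% set_members)
  n <- length(ranked)
  if (!length(pos)) stop("set is disjoint from the ranked list")
  if (length(pos) >= n) stop("set covers the entire ranked list")
  es_from_positions(pos, n)
}

# ES from sorted member positions, exact integer arithmetic over the
# common denominator k*(N-k). Candidate extremes occur just after each
# hit (maxima) and just before each hit or at the list end (minima).
es_from_positions <- function(pos, n) {
  k <- length(pos)
  pos <- sort.int(pos)
  j <- seq_len(k)
  inc <- n - k                       # numerator gain per hit
  dec <- k                           # numerator loss per miss
  at_hit <- j * inc - (pos - j) * dec
  before_hit <- at_hit - inc
  num_max <- max(at_hit)
  num_min <- min(before_hit, 0)
  num <- if (num_max >= -num_min) num_max else num_min
  num / (k * (n - k))
}

#' Run a kinase-set enrichment analysis
#'
#' Builds kinase sets by motif matching (size gate >5 and <1000), ranks
#' peptides by the responder-vs-nonresponder t statistic, scores each set
#' with the classic running-sum statistic, and calibrates it against
#' `n_perm` phenotype-label permutations with full re-ranking. When the
#' number of distinct relabelings is at most `n_perm` the permutations are
#' enumerated exhaustively instead of sampled.
#'
#' Per kinase set: NES is the observed score divided by the mean magnitude
#' of same-sign permutation scores of that set; the permutation p-value is
#' the add-one tail fraction of same-sign permutation scores at least as
#' extreme; the FDR q-value is the GSEA-style ratio of the pooled-null to
#' observed tail fractions at the set's NES, clipped to `[0, 1]`.
#'
#' @param matrix a [phospho_matrix()].
#' @param annotations sample annotation data frame.
#' @param patterns a `motif_library` (see [read_motif_library()]).
#' @param arm optional arm filter, as in [phospho_diff()].
#' @param n_perm number of phenotype permutations (default 1000).
#' @param seed integer seed (substream `"ksea-permutations"`).
#' @param fdr_threshold significance boundary on the q-value (default
#'   0.20).
#' @param log_transform rank on log2(x+1) intensities (default TRUE).
#' @param perm_type `"phenotype"` (default, re-ranks per permutation) or
#'   `"set"` (random member positions, ranking fixed).
#' @param min_size,max_size kinase-set size gate (defaults 6 and 999).
#' @return Object of class `ksea`: `results` data frame (one row per
#'   kinase: `kinase_id`, `set_size`, `es`, `nes`, `p_perm`, `fdr_q`,
#'   `direction`, `significant`), the observed `ranking`, and `barcode`
#'   (per-kinase member positions in the ranked list).
#' @export
ksea <- function(matrix, annotations, patterns,
                 arm = c("all", "standard", "experimental"),
                 n_perm = 1000L, seed = 1L, fdr_threshold = 0.20,
                 log_transform = TRUE,
                 perm_type = c("phenotype", "set"),
                 min_size = 6L, max_size = 999L) {
  arm <- match.arg(arm)
  perm_type <- match.arg(perm_type)
  al <- align_annotations(matrix, annotations)
  ann <- al$annotations
  if (arm != "all") {
    ann <- ann[ann$arm == arm, , drop = FALSE]
    al$matrix <- subset_samples(al$matrix, ann$sample_id)
  }
  mat <- al$matrix
  is_r <- ann$response == "responder"
  if (sum(is_r) < 2L || sum(!is_r) < 2L)
    stop("insufficient data: need >= 2 samples per response group")
  sets <- build_kinase_sets(mat, patterns, min_size = min_size,
                            max_size = max_size)
  if (!length(sets))
    return(structure(list(results = data.frame(), ranking = NULL,
                          barcode = list(), n_perm = n_perm, seed = seed),
                     class = "ksea"))

  pid <- mat$peptides$peptide_id
  n <- length(pid)
  full <- lengths(sets) >= n
  if (any(full)) {
    warning("dropping ", sum(full),
            " kinase set(s) covering the entire peptide list")
    sets <- sets[!full]
    if (!length(sets))
      return(structure(list(results = data.frame(), ranking = NULL,
                            barcode = list(), n_perm = n_perm,
                            seed = seed),
                       class = "ksea"))
  }
  v <- mat$values
  if (log_transform) v <- log2(v + 1)

  t_obs <- row_tstats(v, is_r)
  ord <- order(-t_obs, pid)
  inv <- integer(n); inv[ord] <- seq_len(n)
  member_idx <- lapply(sets, function(m) match(m, pid))
  pos_obs <- lapply(member_idx, function(ix) inv[ix])
  es_obs <- vapply(pos_obs, es_from_positions, 0, n = n)

  n_samp <- ncol(v)
  n1 <- sum(is_r)
  exhaustive <- choose(n_samp, n1) <= n_perm
  perm_seed <- substream_seed(seed, "ksea-permutations")
  if (perm_type == "phenotype") {
    if (exhaustive) {
      message("enumerating all ", choose(n_samp, n1),
              " relabelings exhaustively")
      combs <- utils::combn(n_samp, n1)
      b <- ncol(combs)
      g <- matrix(0, n_samp, b)
      g[cbind(as.vector(combs), rep(seq_len(b), each = n1))] <- 1
    } else {
      b <- n_perm
      g <- with_seed(perm_seed, {
        g0 <- matrix(0, n_samp, b)
        for (j in seq_len(b)) g0[sample.int(n_samp, n1), j] <- 1
        g0
      })
    }
    t_perm <- row_tstats_perm(v, g)
    es_null <- matrix(0, length(sets), b)
    for (jb in seq_len(b)) {
      ob <- order(-t_perm[, jb], pid)
      invb <- integer(n); invb[ob] <- seq_len(n)
      for (s in seq_along(member_idx))
        es_null[s, jb] <- es_from_positions(invb[member_idx[[s]]], n)
    }
  } else {
    b <- n_perm
    es_null <- with_seed(perm_seed, {
      out <- matrix(0, length(sets), b)
      for (s in seq_along(member_idx)) {
        k <- length(member_idx[[s]])
        for (jb in seq_len(b))
          out[s, jb] <- es_from_positions(sample.int(n, k), n)
      }
      out
    })
  }

  stats_df <- normalize_es(es_obs, es_null)
  res <- data.frame(kinase_id = names(sets),
                    set_size = lengths(sets),
                    es = es_obs,
                    nes = stats_df$nes,
                    p_perm = stats_df$p_perm,
                    fdr_q = stats_df$fdr_q,
                    direction = ifelse(es_obs >= 0, "high_in_responders",
                                       "high_in_nonresponders"),
                    significant = stats_df$fdr_q < fdr_threshold,
                    row.names = NULL)
  res <- res[order(-abs(res$nes)), ]
  ranking <- structure(data.frame(peptide_id = pid[ord],
                                  stat = t_obs[ord], row.names = NULL),
                       class = c("ranked_list", "data.frame"))
  structure(list(results = res, ranking = ranking,
                 barcode = lapply(pos_obs, sort.int),
                 n_peptides = n, n_perm = b, seed = seed,
                 exhaustive = exhaustive, perm_type = perm_type,
                 fdr_threshold = fdr_threshold),
            class = "ksea")
}

# NES, permutation p and GSEA-style FDR q from observed and null scores.
normalize_es <- function(es_obs, es_null) {
  n_set <- length(es_obs)
  mu_pos <- apply(es_null, 1, function(z) mean(z[z > 0]))
  mu_neg <- apply(es_null, 1, function(z) mean(abs(z[z < 0])))
  mu_all <- rowMeans(abs(es_null))
  mu_pos[!is.finite(mu_pos) | mu_pos == 0] <-
    mu_all[!is.finite(mu_pos) | mu_pos == 0]
  mu_neg[!is.finite(mu_neg) | mu_neg == 0] <-
    mu_all[!is.finite(mu_neg) | mu_neg == 0]
  mu_pos[mu_pos == 0] <- 1
  mu_neg[mu_neg == 0] <- 1

  nes <- ifelse(es_obs >= 0, es_obs / mu_pos, es_obs / mu_neg)
  nes_null <- es_null / ifelse(es_null >= 0, mu_pos, mu_neg)

  p_perm <- numeric(n_set)
  for (s in seq_len(n_set)) {
    z <- es_null[s, ]
    same <- if (es_obs[s] >= 0) z[z >= 0] else z[z < 0]
    p_perm[s] <- (1 + sum(abs(same) >= abs(es_obs[s]) - 1e-12)) /
      (1 + length(same))
  }

  null_pos <- nes_null[nes_null >= 0]
  null_neg <- nes_null[nes_null < 0]
  obs_pos <- nes[nes >= 0]
  obs_neg <- nes[nes < 0]
  fdr_q <- vapply(seq_len(n_set), function(s) {
    if (nes[s] >= 0) {
      num <- if (length(null_pos)) mean(null_pos >= nes[s] - 1e-12) else 0
      den <- mean(obs_pos >= nes[s] - 1e-12)
    } else {
      num <- if (length(null_neg)) mean(null_neg <= nes[s] + 1e-12) else 0
      den <- mean(obs_neg <= nes[s] + 1e-12)
    }
    min(1, max(0, num / max(den, .Machine$double.eps)))
  }, 0)
  list(nes = nes, p_perm = p_perm, fdr_q = fdr_q)
}

#' @export
print.ksea <- function(x, ...) {
  cat("Kinase-set enrichment analysis:", nrow(x$results), "kinase sets,",
      x$n_peptides, "ranked peptides\n")
  cat("  permutations:", x$n_perm, if (isTRUE(x$exhaustive))
    "(exhaustive)" else "(sampled)", "; scheme:", x$perm_type, "\n")
  sig <- x$results[x$results$significant, , drop = FALSE]
  cat("  significant at FDR <", x$fdr_threshold, ":", nrow(sig), "\n")
  if (nrow(sig))
    print(utils::head(sig[, c("kinase_id", "set_size", "nes", "p_perm",
                              "fdr_q", "direction")], 10), row.names = FALSE)
  invisible(x)
}

#' @export
summary.ksea <- function(object, ...) {
  res <- object$results
  cat("Kinase sets tested:", nrow(res), "\n")
  if (nrow(res)) {
    cat("NES range:", sprintf("[%.2f, %.2f]", min(res$nes), max(res$nes)),
        "\n")
    print(res[, c("kinase_id", "set_size", "es", "nes", "p_perm", "fdr_q",
                  "direction", "significant")], row.names = FALSE)
  }
  invisible(res)
}

#' @export
as.data.frame.ksea <- function(x, ...) x$results

#' Barcode (running-sum) plot for one kinase set
#'
#' Draws the classic enrichment running sum over the ranked peptide list;
#' each vertical tick marks a member phosphopeptide's position.
#'
#' @param x a `ksea` object.
#' @param kinase_id kinase to plot (default: the top-|NES| kinase).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ksea <- function(x, kinase_id = NULL, ...) {
  if (!nrow(x$results)) stop("no kinase sets to plot")
  if (is.null(kinase_id)) kinase_id <- x$results$kinase_id[1]
  pos <- x$barcode[[kinase_id]]
  if (is.null(pos)) stop("unknown kinase: ", kinase_id)
  n <- x$n_peptides; k <- length(pos)
  step <- rep(-1 / (n - k), n)
  step[pos] <- 1 / k
  rs <- cumsum(step)
  graphics::plot(seq_len(n), rs, type = "l", xlab = "rank in peptide list",
                 ylab = "running enrichment", main = kinase_id, ...)
  graphics::abline(h = 0, col = "grey70")
  graphics::rug(pos, col = "black")
  invisible(x)
}

#' Barcode coordinates for every kinase set
#'
#' @param x a `ksea` object.
#' @return Data frame `kinase_id`, `position` (member positions in the
#'   ranked list), suitable for writing alongside the result table.
#' @export
ksea_barcode <- function(x) {
  stopifnot(inherits(x, "ksea"))
  if (!length(x$barcode))
    return(data.frame(kinase_id = character(0), position = integer(0)))
  data.frame(kinase_id = rep(names(x$barcode), lengths(x$barcode)),
             position = unlist(x$barcode, use.names = FALSE))
}
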