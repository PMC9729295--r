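# Independent oracles and small fixture builders shared across tests.

# Brute-force classic enrichment score: full integer running sum over the
# ranked list (gain N-k per hit, lose k per miss, common denominator
# k*(N-k)), extreme of largest magnitude, positive preferred on a tie.
es_brute_force <- function(ranked_ids, members) {
  hit <- ranked_ids %in% members
  n <- length(ranked_ids)
  k <- sum(hit)
  step <- ifelse(hit, n - k, -k)
  rs <- cumsum(step)
  mx <- max(rs)
  mn <- min(rs)
  num <- if (mx >= -mn) mx else mn
  num / (k * (n - k))
}

# Exact two-sided permutation p-value of the Mann-Whitney U statistic,
# computed by pair counting (U = #{x_i > y_j} + 0.5 #{x_i == y_j}) over
# every relabeling -- an independent route from the package's rank-sum
# implementation.
mww_pair_count_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  e_u <- n1 * (n - n1) / 2
  obs <- abs(u_of(seq_len(n1)) - e_u)
  combs <- utils::combn(n, n1)
  stat <- apply(combs, 2, function(idx) abs(u_of(idx) - e_u))
  mean(stat >= obs - 1e-9)
}

# Hand step-up BH oracle: q_i = min over j with p_(j) >= p_(i) of
# m * p_(j) / j, clipped at 1.
bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# Small well-formed intensity matrix for I/O and pipeline tests.
make_test_matrix <- function(n_pep = 3L, n_samp = 4L, seed = 1L) {
  set.seed(seed)
  vals <- matrix(round(2^rnorm(n_pep * n_samp, 15, 2), 3), n_pep, n_samp)
  peptides <- data.frame(
    peptide_id = sprintf("pep%03d", seq_len(n_pep)),
    protein_ids = sprintf("PROT%03d;PROT%03d", seq_len(n_pep),
                          seq_len(n_pep) + 100L),
    residue = rep(c("S", "T", "Y"), length.out = n_pep),
    site_position = seq_len(n_pep) * 10L,
    sequence_window = vapply(seq_len(n_pep), function(i) {
      w <- sample(strsplit("ACDEFGHIKLMNPQRVW", "")[[1]], 15,
                  replace = TRUE)
      w[8] <- rep(c("S", "T", "Y"), length.out = n_pep)[i]
      paste(w, collapse = "")
    }, ""))
  phospho_matrix(vals, peptides, sprintf("S%02d", seq_len(n_samp)))
}

# Peptide metadata whose sequence windows carry a chosen anchor letter at
# a chosen offset, for controlled motif-matching fixtures.
make_anchored_peptides <- function(n, anchor, offset = -3L,
                                   residue = "S", prefix = "pep") {
  windows <- vapply(seq_len(n), function(i) {
    w <- rep("A", 15)
    w[8] <- residue
    w[8 + offset] <- anchor
    paste(w, collapse = "")
  }, "")
  data.frame(peptide_id = sprintf("%s%04d", prefix, seq_len(n)),
             protein_ids = sprintf("PR%04d", seq_len(n)),
             residue = residue, site_position = 5L,
             sequence_window = windows)
}
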