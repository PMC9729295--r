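test_that("motif patterns parse offsets, wildcards, brackets and acceptors", {
  p <- parse_motif("R-X-X-pS/pT", "K1")
  expect_equal(p$offsets, c(-3L, 0L))
  expect_equal(p$allowed[[1]], "R")
  expect_setequal(p$allowed[[2]], c("S", "T"))

  p2 <- parse_motif("[RK]-X-X-pS-P", "K2")
  expect_equal(p2$offsets, c(-3L, 0L, 1L))
  expect_setequal(p2$allowed[[1]], c("R", "K"))
  expect_equal(p2$allowed[[3]], "P")

  expect_error(parse_motif("R-X-X"), "phosphoacceptor")
  expect_error(parse_motif("R-?-pS"), "cannot parse")
  expect_error(parse_motif("R-X-X-X-X-X-X-X-X-pS"), "offset")
})

test_that("motif matching honours constraints and never matches padding", {
  pats <- list(parse_motif("[RK]-X-X-pS/pT", "K1"))
  win_match <- "AAAARAASAAAAAAA"
  win_miss <- "AAAAGAASAAAAAAA"
  expect_equal(match_motifs(win_match, "S", pats), "K1")
  expect_length(match_motifs(win_miss, "S", pats), 0)
  expect_length(match_motifs(win_match, "Y", pats), 0)

  win_pad <- "____RAASAAAAAAA"
  expect_equal(match_motifs(win_pad, "S", pats), "K1")
  win_pad2 <- "AAAA_AASAAAAAAA"
  expect_length(match_motifs(win_pad2, "S", pats), 0)

  expect_length(match_motifs(win_match, "S", list()), 0)
  expect_error(match_motifs("SHORT", "S", pats), "15")
})

test_that("kinase sets respect the >5 and <1000 size gate", {
  pep <- rbind(make_anchored_peptides(5, "R", prefix = "ra"),
               make_anchored_peptides(6, "K", prefix = "kb"),
               make_anchored_peptides(1000, "H", prefix = "hc"),
               make_anchored_peptides(999, "W", prefix = "wd"))
  vals <- matrix(1, nrow(pep), 4)
  mat <- phospho_matrix(vals, pep, sprintf("S%d", 1:4))
  pats <- list(parse_motif("R-X-X-pS", "FIVE"),
               parse_motif("K-X-X-pS", "SIX"),
               parse_motif("H-X-X-pS", "THOUSAND"),
               parse_motif("W-X-X-pS", "NNN"))
  sets <- suppressMessages(build_kinase_sets(mat, pats))
  expect_setequal(names(sets), c("SIX", "NNN"))
  expect_equal(lengths(sets)[["SIX"]], 6L)
  expect_equal(lengths(sets)[["NNN"]], 999L)
  excluded <- attr(sets, "excluded")
  expect_setequal(excluded$kinase_id, c("FIVE", "THOUSAND"))
})

test_that("t-statistic ranking matches t.test and breaks ties by id", {
  pep <- make_anchored_peptides(3, "R")
  vals <- rbind(2^c(3, 4, 5, 0, 1, 2) - 1,   # log2(v+1) = 3,4,5 | 0,1,2
                rep(7, 6),                    # zero variance -> t = 0
                rep(c(3, 0), each = 3))       # zero pooled variance
  mat <- phospho_matrix(vals, pep, sprintf("S%d", 1:6))
  is_r <- rep(c(TRUE, FALSE), each = 3)
  rk <- rank_by_tstat(mat, is_r, log_transform = TRUE)
  t_ref <- unname(t.test(c(3, 4, 5), c(0, 1, 2),
                         var.equal = TRUE)$statistic)
  expect_equal(rk$stat[rk$peptide_id == "pep0001"], t_ref)
  expect_equal(t_ref, 3 * sqrt(1.5), tolerance = 1e-12)
  # both degenerate rows get t = 0 and sort lexicographically
  expect_equal(rk$peptide_id, c("pep0001", "pep0002", "pep0003"))
  expect_equal(rk$stat[2:3], c(0, 0))

  set.seed(77)
  vals2 <- matrix(rnorm(10 * 8, 10, 2), 10, 8)
  mat2 <- phospho_matrix(abs(vals2), make_anchored_peptides(10, "R"),
                         sprintf("S%d", 1:8))
  is_r2 <- rep(c(TRUE, FALSE), each = 4)
  rk2 <- rank_by_tstat(mat2, is_r2, log_transform = FALSE)
  for (pid in rk2$peptide_id) {
    i <- match(pid, mat2$peptides$peptide_id)
    t_ref <- unname(t.test(mat2$values[i, is_r2], mat2$values[i, !is_r2],
                           var.equal = TRUE)$statistic)
    expect_equal(rk2$stat[rk2$peptide_id == pid], t_ref,
                 tolerance = 1e-10)
  }
})

test_that("classic enrichment score matches worked values and the
           brute-force oracle exactly", {
  expect_equal(enrichment_score_classic(letters[1:4], c("a", "b")), 1)
  expect_equal(enrichment_score_classic(letters[1:4], "d"), -1)
  expect_equal(enrichment_score_classic(letters[1:5], "b"), 0.75)

  set.seed(101)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    ids <- sample(LETTERS, n)
    k <- sample(seq_len(n - 1), 1)
    members <- sample(ids, k)
    expect_identical(enrichment_score_classic(ids, members),
                     es_brute_force(ids, members))
  }
})

test_that("ES depends only on rank order and negates under list reversal", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    ids <- sample(letters, n)
    k <- sample(seq_len(n - 1), 1)
    members <- sample(ids, k)
    scores <- sort(rnorm(n), decreasing = TRUE)
    ord1 <- ids[order(-scores)]
    ord2 <- ids[order(-exp(scores))]   # monotone transform of scores
    expect_identical(enrichment_score_classic(ord1, members),
                     enrichment_score_classic(ord2, members))
    es_f <- enrichment_score_classic(ids, members)
    es_r <- enrichment_score_classic(rev(ids), members)
    # antisymmetry holds whenever the extreme is unique (no +/- tie)
    hit <- ids %in% members
    rs <- cumsum(ifelse(hit, n - k, -k))
    if (max(rs) != -min(rs)) expect_identical(es_r, -es_f)
    expect_equal(abs(es_r), abs(es_f))
  }
})

test_that("ES agrees with fgsea's unweighted statistic", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    stats <- sort(rnorm(n), decreasing = TRUE)
    names(stats) <- sprintf("g%03d", seq_len(n))
    k <- sample(2:(n - 2), 1)
    pos <- sort(sample(seq_len(n), k))
    rs <- cumsum(ifelse(seq_len(n) %in% pos, n - k, -k))
    if (max(rs) == -min(rs)) next   # +/- tie: conventions differ
    es_pkg <- enrichment_score_classic(names(stats), names(stats)[pos])
    es_ref <- fgsea::calcGseaStat(stats, selectedStats = pos,
                                  gseaParam = 0)
    expect_equal(es_pkg, es_ref, tolerance = 1e-12)
  }
})

test_that("ksea is seed-deterministic, gate-respecting and recovers a
           planted kinase", {
  cfg <- phospho_sim_config(n_responders = 10, n_nonresponders = 10,
                            n_peptides = 400, n_kinases = 15,
                            substrates_per_kinase = 12,
                            planted_kinases = data.frame(
                              kinase_id = "KIN007", log2_effect = 2),
                            seed = 19)
  sim <- simulate_phospho_dataset(cfg)
  k1 <- ksea(sim$matrix, sim$annotations, sim$motifs, n_perm = 300,
             seed = 5)
  k2 <- ksea(sim$matrix, sim$annotations, sim$motifs, n_perm = 300,
             seed = 5)
  expect_identical(k1$results, k2$results)
  expect_true(all(k1$results$set_size > 5 & k1$results$set_size < 1000))
  expect_true(all(abs(k1$results$es) <= 1))
  expect_true(all(sign(k1$results$nes) == sign(k1$results$es) |
                    k1$results$es == 0))
  top <- k1$results$kinase_id[which.max(k1$results$nes)]
  expect_equal(top, "KIN007")
  expect_lt(k1$results$fdr_q[k1$results$kinase_id == "KIN007"], 0.20)
  expect_equal(
    k1$results$direction[k1$results$kinase_id == "KIN007"],
    "high_in_responders")
})

test_that("ksea falls back to exhaustive enumeration for tiny cohorts and
           normalizes degenerate constant data to NES 1", {
  pep <- rbind(make_anchored_peptides(20, "R", prefix = "aa"),
               make_anchored_peptides(5, "K", prefix = "zz"))
  vals <- matrix(5, 25, 6)
  mat <- phospho_matrix(vals, pep, sprintf("S%d", 1:6))
  ann <- data.frame(sample_id = mat$samples, arm = "standard",
                    response = rep(c("responder", "nonresponder"),
                                   each = 3))
  pats <- list(parse_motif("R-X-X-pS", "KA"))
  expect_message(
    k <- ksea(mat, ann, pats, n_perm = 1000, seed = 1, max_size = 999),
    "exhaustive")
  expect_true(k$exhaustive)
  expect_equal(k$n_perm, choose(6, 3))
  expect_equal(k$results$nes, 1)
  expect_equal(k$results$p_perm, 1)
})

test_that("set-permutation scheme gives calibrated null scores", {
  cfg <- phospho_sim_config(n_responders = 8, n_nonresponders = 8,
                            n_peptides = 300, n_kinases = 20,
                            substrates_per_kinase = 10, seed = 44)
  sim <- simulate_phospho_dataset(cfg)
  ks <- ksea(sim$matrix, sim$annotations, sim$motifs, n_perm = 400,
             seed = 9, perm_type = "set")
  expect_equal(nrow(ks$results), 20L)
  expect_gt(min(ks$results$p_perm), 0.001)
})
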