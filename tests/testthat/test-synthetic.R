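test_that("generators are deterministic given config and seed", {
  cfg <- phospho_sim_config(n_responders = 4, n_nonresponders = 4,
                            n_peptides = 120, n_kinases = 10,
                            substrates_per_kinase = 6,
                            exclusive_fraction = 0.05, seed = 11)
  a <- simulate_phospho_dataset(cfg)
  b <- simulate_phospho_dataset(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$matrix$peptides, b$matrix$peptides)
  expect_identical(a$truth, b$truth)

  icfg <- ihc_sim_config(n_patients = 40, seed = 3)
  expect_identical(simulate_ihc_cohort(icfg), simulate_ihc_cohort(icfg))

  p1 <- simulate_pulldown_tables(50, replicates = 2, seed = 9)
  p2 <- simulate_pulldown_tables(50, replicates = 2, seed = 9)
  expect_identical(p1$bait, p2$bait)
  expect_identical(p1$igg, p2$igg)
})

test_that("substrate assignment is consistent with the emitted motifs", {
  cfg <- phospho_sim_config(n_responders = 3, n_nonresponders = 3,
                            n_peptides = 150, n_kinases = 12,
                            substrates_per_kinase = 8, seed = 5)
  sim <- simulate_phospho_dataset(cfg)
  assign <- sim$truth$assignment
  pep <- sim$matrix$peptides
  for (i in seq_len(nrow(pep))) {
    kins <- match_motifs(pep$sequence_window[i], pep$residue[i],
                         sim$motifs)
    expected <- assign$kinase_id[i]
    if (is.na(expected)) {
      expect_length(kins, 0)
    } else {
      expect_identical(kins, expected)
    }
  }
})

test_that("null configuration carries no planted structure", {
  cfg <- phospho_sim_config(n_responders = 10, n_nonresponders = 10,
                            n_peptides = 400, n_kinases = 20,
                            substrates_per_kinase = 8,
                            exclusive_fraction = 0, seed = 21)
  sim <- simulate_phospho_dataset(cfg)
  expect_equal(nrow(sim$truth$planted_kinases), 0L)
  expect_equal(nrow(sim$truth$exclusive), 0L)
  is_r <- sim$annotations$response == "responder"
  lv <- log2(sim$matrix$values + 1)
  diff_means <- rowMeans(lv[, is_r]) - rowMeans(lv[, !is_r])
  expect_lt(abs(mean(diff_means)), 0.1)
})

test_that("planted kinase effects shift substrate intensities as configured", {
  cfg <- phospho_sim_config(n_responders = 20, n_nonresponders = 20,
                            n_peptides = 200, n_kinases = 1,
                            substrates_per_kinase = 30,
                            planted_kinases = data.frame(
                              kinase_id = "KIN001", log2_effect = 2),
                            dropout_baseline = 0, seed = 8)
  sim <- simulate_phospho_dataset(cfg)
  subs <- sim$truth$assignment$kinase_id == "KIN001" &
    !is.na(sim$truth$assignment$kinase_id)
  is_r <- sim$annotations$response == "responder"
  lv <- log2(sim$matrix$values)
  d <- rowMeans(lv[subs, is_r]) - rowMeans(lv[subs, !is_r])
  # per-substrate difference has variance sd^2*(1/20+1/20) = 0.1
  se <- sqrt(0.1 / sum(subs))
  expect_lt(abs(mean(d) - 2), 3 * se)
})

test_that("group-exclusive peptides are zeroed in exactly the recorded group", {
  cfg <- phospho_sim_config(n_responders = 5, n_nonresponders = 5,
                            n_peptides = 200, n_kinases = 5,
                            substrates_per_kinase = 6,
                            dropout_baseline = 0,
                            exclusive_fraction = 0.2, seed = 13)
  sim <- simulate_phospho_dataset(cfg)
  excl <- sim$truth$exclusive
  expect_equal(nrow(excl), 40L)
  is_r <- sim$annotations$response == "responder"
  for (i in seq_len(nrow(excl))) {
    row <- sim$matrix$values[excl$peptide_id[i], ]
    zero_r <- excl$zero_group[i] == "responder"
    expect_true(all(row[if (zero_r) is_r else !is_r] == 0))
    expect_true(all(row[if (zero_r) !is_r else is_r] > 0))
  }
})

test_that("IHC cohort: perfect marker correlation gives identical quartile
           membership and equal rates give a null risk ratio", {
  cfg <- ihc_sim_config(n_patients = 100, markers = c("M1", "M2"),
                        marker_correlation = 1, seed = 4)
  rec <- simulate_ihc_cohort(cfg)
  h1 <- rec$h_score[rec$marker == "M1"]
  h2 <- rec$h_score[rec$marker == "M2"]
  expect_identical(as.character(quartile_categorize(h1)),
                   as.character(quartile_categorize(h2)))

  null_cfg <- ihc_sim_config(n_patients = 400, markers = "M1",
                             pcr_rate_low = 0.5,
                             pcr_rate_upper_quartile = 0.5, seed = 6)
  rec0 <- simulate_ihc_cohort(null_cfg)
  assoc <- association_test(rec0, m_comparisons = 1)
  expect_gt(assoc$risk_ratio, 0.65)
  expect_lt(assoc$risk_ratio, 1.5)
})

test_that("IHC cohort risk ratio recovers the generating rate ratio", {
  hits <- 0L
  for (rep in 1:100) {
    cfg <- ihc_sim_config(n_patients = 400, markers = "M1",
                          pcr_rate_low = 0.30,
                          pcr_rate_upper_quartile = 0.90,
                          seed = 1000 + rep)
    rec <- simulate_ihc_cohort(cfg)
    rr <- association_test(rec, m_comparisons = 1)$risk_ratio
    if (rr >= 2.4 && rr <= 3.6) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("pull-down generator: background is unenriched, planted proteins
           pass the candidate filter by construction", {
  tbl <- simulate_pulldown_tables(301, replicates = 2, seed = 17)
  scr <- pulldown_screen(tbl)
  expect_lte(sum(scr$points$is_candidate), 2L)
  expect_equal(median(scr$table$bait[, 1] / scr$table$igg[, 1]), 1)

  planted <- data.frame(protein_id = "CLIP170", bait_log2_enrichment = 5)
  tbl2 <- simulate_pulldown_tables(200, planted = planted,
                                   replicates = 2, seed = 18,
                                   igg_absent = "CLIP170")
  scr2 <- pulldown_screen(tbl2)
  pt <- scr2$points[scr2$points$protein_id == "CLIP170", ]
  expect_true(pt$is_candidate)
  expect_true(pt$igg_undetected)
})

test_that("simulated datasets round-trip to disk in the package dialects", {
  cfg <- phospho_sim_config(n_responders = 3, n_nonresponders = 3,
                            n_peptides = 60, n_kinases = 5,
                            substrates_per_kinase = 7, seed = 2)
  sim <- simulate_phospho_dataset(cfg)
  dir <- withr::local_tempdir()
  paths <- write_simulated_dataset(sim, dir)
  mat <- read_intensity_table(paths[["matrix"]])
  expect_equal(mat$values, sim$matrix$values, tolerance = 1e-12)
  ann <- read_sample_annotations(paths[["annotations"]])
  expect_equal(ann$response, sim$annotations$response)
  motifs <- read_motif_library(paths[["motifs"]])
  expect_length(motifs, length(sim$motifs))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_named(truth, c("planted_kinases", "assignment", "exclusive"))
})
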