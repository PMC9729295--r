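test_that("H-score evaluates the area-weighted formula and validates input", {
  expect_equal(h_score(100, 0, 0), 3.0)
  expect_equal(h_score(0, 0, 0), 0.0)
  expect_equal(h_score(50, 30, 20), 2.3)
  expect_equal(h_score(c(100, 0), c(0, 0), c(0, 50)), c(3, 0.5))
  expect_error(h_score(60, 30, 20), "sum")
  expect_error(h_score(-1, 0, 0), "\\[0, 100\\]")
  expect_error(h_score(101, 0, 0), "\\[0, 100\\]")
})

test_that("upper-quartile dichotomization uses a strict cutoff", {
  g <- quartile_categorize(c(1, 2, 3, 4))
  expect_equal(attr(g, "cutoff"), 3.25)
  expect_identical(as.character(g), c("Low", "Low", "Low", "High"))
  expect_identical(as.character(quartile_categorize(rep(2, 8))),
                   rep("Low", 8))
  expect_identical(as.character(quartile_categorize(c(0, 0, 0, 10))),
                   c("Low", "Low", "Low", "High"))
  expect_error(quartile_categorize(c(1, 2, 3)), "insufficient data")
})

test_that("association test reproduces hand-computed effect measures", {
  # 40 patients: top 10 h-scores High (8 pCR), 30 Low (9 pCR)
  rec <- data.frame(marker = "M",
                    h_score = 1:40,
                    pcr = c(rep(c(TRUE, FALSE), c(9, 21)),
                            rep(c(TRUE, FALSE), c(8, 2))))
  a <- association_test(rec, m_comparisons = 1)
  expect_equal(a$n_q1, 10L)
  expect_equal(a$pcr_q1, 8L)
  expect_equal(a$risk_ratio, (8 / 10) / (9 / 30))
  expect_equal(a$odds_ratio, (8 * 21) / (2 * 9))
  expect_false(a$haldane_corrected)

  # chi-square equals the textbook sum over (O-E)^2/E
  tab <- rbind(c(8, 2), c(9, 21))
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(a$chi2_stat, sum((tab - e)^2 / e))
  expect_equal(a$p_bonferroni, min(1, a$p_raw))
})

test_that("null tables give unit risk ratio and p = 1", {
  rec <- data.frame(h_score = 1:40,
                    pcr = rep(c(TRUE, FALSE), 20))  # 5/10 vs 15/30
  a <- association_test(rec, m_comparisons = 5)
  expect_equal(a$risk_ratio, 1)
  expect_equal(a$chi2_stat, 0)
  expect_equal(a$p_raw, 1)
  expect_equal(a$call, "ns")
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  rec <- data.frame(h_score = 1:20,
                    pcr = c(rep(FALSE, 15), rep(TRUE, 5)))
  a <- association_test(rec, m_comparisons = 1)
  expect_true(a$haldane_corrected)
  expect_equal(a$odds_ratio, (5.5 * 15.5) / (0.5 * 0.5))
  expect_true(is.finite(a$chi2_stat))
})

test_that("chi-square matches the textbook formula on random 2x2 tables", {
  set.seed(14)
  reps <- 0L
  while (reps < 20L) {
    n_hi <- sample(5:12, 1)
    n_lo <- sample(5:18, 1)
    p_hi <- runif(1, 0.2, 0.8); p_lo <- runif(1, 0.2, 0.8)
    pcr <- c(runif(n_hi) < p_hi, runif(n_lo) < p_lo)
    if (length(unique(pcr)) < 2) next
    rec <- data.frame(h_score = seq_len(n_hi + n_lo), pcr = rev(pcr))
    a <- tryCatch(association_test(rec, 1), error = function(e) NULL)
    if (is.null(a)) next
    tab <- rbind(c(a$pcr_q1, a$n_q1 - a$pcr_q1),
                 c(a$pcr_rest, a$n_rest - a$pcr_rest))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(a$chi2_stat, sum((tab - e)^2 / e), tolerance = 1e-12)
    reps <- reps + 1L
  }
})

test_that("bonferroni bands classify adjusted p-values", {
  mk <- function(p_hi) {
    # 200 patients, planted difference controls p
    rec <- data.frame(h_score = 1:200,
                      pcr = c(runif(150) < 0.3, runif(50) < p_hi))
    association_test(rec, m_comparisons = 5)
  }
  set.seed(9)
  strong <- mk(0.95)
  expect_equal(strong$call, "significant")
  expect_equal(strong$p_bonferroni, min(1, 5 * strong$p_raw))
})

test_that("combined marker stratum reports rate, SE and comparison", {
  cfg <- ihc_sim_config(n_patients = 400, markers = c("CDK4", "FLNA"),
                        pcr_rate_low = 0.30,
                        pcr_rate_upper_quartile = 0.90,
                        marker_correlation = 0.8, seed = 23)
  rec <- simulate_ihc_cohort(cfg)
  cm <- combined_marker_rate(rec, "CDK4", "FLNA")
  expect_equal(cm$status, "ok")
  expect_gt(cm$n_both_q1, 20)
  expect_lt(abs(cm$pcr_rate_both_q1 - 0.9),
            3 * sqrt(0.9 * 0.1 / cm$n_both_q1))
  expect_lt(cm$p_value, 1e-6)

  # anti-correlated markers: nobody lands in both upper quartiles
  anti <- data.frame(patient_id = rep(sprintf("p%02d", 1:20), 2),
                     marker = rep(c("A", "B"), each = 20),
                     h_score = c(1:20, 20:1),
                     pcr = rep(c(TRUE, FALSE), 20))
  cm2 <- combined_marker_rate(anti, "A", "B")
  expect_equal(cm2$status, "empty_stratum")
  expect_equal(cm2$n_both_q1, 0L)
})

test_that("marker correlations follow the Pearson formula", {
  x <- c(1, 2, 3)
  expect_equal(marker_correlation(x, 2 * x + 1)$pearson_r, 1)
  expect_equal(marker_correlation(x, -x)$pearson_r, -1)
  expect_equal(marker_correlation(x, c(1, 3, 2))$pearson_r, 0.5)
  expect_error(marker_correlation(x, c(2, 2, 2)), "zero variance")
  expect_error(marker_correlation(x, c(1, 2)), "paired")
})

test_that("ihc_screen runs one association per marker under shared m", {
  cfg <- ihc_sim_config(n_patients = 120, markers = c("CDK4", "FLNA"),
                        seed = 31)
  rec <- simulate_ihc_cohort(cfg)
  scr <- ihc_screen(rec, m_comparisons = 5)
  expect_equal(nrow(scr), 2L)
  expect_setequal(scr$marker, c("CDK4", "FLNA"))
  expect_true(all(scr$p_bonferroni >= scr$p_raw - 1e-12))
  expect_true(all(scr$call %in% c("significant", "borderline", "ns")))
})
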