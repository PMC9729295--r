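# Seeded synthetic-data generators. These emulate the statistical
# structure the analysis assumes -- log-normal phosphopeptide intensities
# with intensity-dependent (missing-not-at-random) dropout, planted
# kinase-substrate activation in responders, group-exclusive peptides,
# IHC cohorts with an upper-quartile/pCR association, and pull-down
# tables with planted bait-specific interactors -- so every stage is
# testable without raw trial data. One global seed is fanned out to named
# substreams per generator.

# Residues available for synthetic motif anchors. Three letters (A, C, G)
# are reserved for non-substrate windows so that kinase membership stays
# unambiguous for truth checking.
.ANCHOR_AA <- setdiff(.AA, c("A", "C", "G"))
.NULL_AA <- c("A", "C", "G")

#' Configuration for the synthetic phosphoproteomic dataset
#'
#' Defaults define a 20-vs-20 cohort with intensities around 2^15
#' (log2-normal, between-peptide sd 2, within-sample sd 1), mild
#' intensity-dependent dropout and no planted effects; planted kinases add
#' a log2 shift to their substrates in responders only.
#'
#' @param n_responders,n_nonresponders samples per response group (>= 2).
#' @param n_peptides total phosphopeptides.
#' @param n_kinases number of kinases with synthetic motifs (each gets
#'   `substrates_per_kinase` dedicated substrate peptides; at most 289
#'   kinases are supported by the disjoint anchor scheme).
#' @param substrates_per_kinase substrates assigned to each kinase.
#' @param planted_kinases data frame with columns `kinase_id` and
#'   `log2_effect`, or `NULL` for a global null.
#' @param baseline_log2_mean,baseline_log2_sd log2-scale mean and
#'   between-peptide sd of the intensity baseline.
#' @param within_log2_sd within-group (sample-to-sample) log2 sd.
#' @param dropout_baseline,dropout_shift_per_log2 detection dropout:
#'   a cell with underlying log2 intensity `v` is set to 0 with
#'   probability `clamp(dropout_baseline - dropout_shift_per_log2 * v)`,
#'   so dim cells drop out more often.
#' @param exclusive_fraction fraction of peptides forced to 0 in one
#'   randomly chosen response group (the lateral volcano clouds).
#' @param arm treatment arm recorded for every sample.
#' @param seed integer seed.
#' @return A `phospho_sim_config` list.
#' @export
phospho_sim_config <- function(n_responders = 20L, n_nonresponders = 20L,
                               n_peptides = 2000L, n_kinases = 250L,
                               substrates_per_kinase = 8L,
                               planted_kinases = NULL,
                               baseline_log2_mean = 15,
                               baseline_log2_sd = 2,
                               within_log2_sd = 1,
                               dropout_baseline = 0.8,
                               dropout_shift_per_log2 = 0.05,
                               exclusive_fraction = 0,
                               arm = "standard",
                               seed = 1L) {
  cfg <- list(n_responders = as.integer(n_responders),
              n_nonresponders = as.integer(n_nonresponders),
              n_peptides = as.integer(n_peptides),
              n_kinases = as.integer(n_kinases),
              substrates_per_kinase = as.integer(substrates_per_kinase),
              planted_kinases = planted_kinases,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              within_log2_sd = within_log2_sd,
              dropout_baseline = dropout_baseline,
              dropout_shift_per_log2 = dropout_shift_per_log2,
              exclusive_fraction = exclusive_fraction,
              arm = arm, seed = as.integer(seed))
  if (cfg$n_responders < 2L || cfg$n_nonresponders < 2L)
    stop_validation("need at least 2 samples per response group")
  if (cfg$substrates_per_kinase < 1L)
    stop_validation("substrates_per_kinase must be >= 1")
  if (cfg$n_kinases > length(.ANCHOR_AA)^2)
    stop_validation("at most ", length(.ANCHOR_AA)^2,
                    " kinases supported by the disjoint anchor scheme")
  if (cfg$n_kinases * cfg$substrates_per_kinase > cfg$n_peptides)
    stop_validation("not enough peptides for the requested kinase sets")
  for (f in c("dropout_baseline", "exclusive_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_validation(f, " must be a probability in [0, 1]")
  if (cfg$dropout_shift_per_log2 < 0)
    stop_validation("dropout_shift_per_log2 must be >= 0")
  if (!is.null(planted_kinases)) {
    pk <- as.data.frame(planted_kinases)
    if (!all(c("kinase_id", "log2_effect") %in% names(pk)))
      stop_validation("planted_kinases needs columns kinase_id, log2_effect")
    cfg$planted_kinases <- pk
  }
  class(cfg) <- "phospho_sim_config"
  cfg
}

#' Simulate a phosphoproteomic dataset with known truth
#'
#' Draws log2-normal intensities, assigns disjoint substrate sets to
#' synthetic kinases via two-residue motif anchors, plants the configured
#' responder activation effects, applies intensity-dependent dropout and
#' group-exclusive detection, and emits the motif library consistent with
#' the kinase-substrate assignment plus a truth record. Fully reproducible
#' from the seed.
#'
#' @param config a [phospho_sim_config()].
#' @return List with `matrix` (a [phospho_matrix()]), `annotations`,
#'   `motifs` (a `motif_library`) and `truth` (planted kinases and
#'   effects, substrate assignment, exclusive peptides).
#' @export
simulate_phospho_dataset <- function(config) {
  stopifnot(inherits(config, "phospho_sim_config"))
  cfg <- config
  n_r <- cfg$n_responders; n_n <- cfg$n_nonresponders
  n_samp <- n_r + n_n
  n_pep <- cfg$n_peptides

  samples <- c(sprintf("R%03d", seq_len(n_r)),
               sprintf("N%03d", seq_len(n_n)))
  is_r <- c(rep(TRUE, n_r), rep(FALSE, n_n))
  ann <- data.frame(sample_id = samples, arm = cfg$arm,
                    response = ifelse(is_r, "responder", "nonresponder"),
                    site = NA_character_)

  kinase_ids <- sprintf("KIN%03d", seq_len(cfg$n_kinases))
  combos <- expand.grid(a1 = .ANCHOR_AA, a2 = .ANCHOR_AA,
                        stringsAsFactors = FALSE)
  combos <- combos[seq_len(cfg$n_kinases), , drop = FALSE]

  assignment <- rep(NA_character_, n_pep)
  if (cfg$n_kinases > 0L)
    assignment[seq_len(cfg$n_kinases * cfg$substrates_per_kinase)] <-
      rep(kinase_ids, each = cfg$substrates_per_kinase)

  peptides <- with_seed(substream_seed(cfg$seed, "phospho-peptides"), {
    residue <- sample(c("S", "T", "Y"), n_pep, replace = TRUE,
                      prob = c(0.75, 0.2, 0.05))
    wm <- matrix(sample(.AA, n_pep * .WINDOW_WIDTH, replace = TRUE),
                 n_pep, .WINDOW_WIDTH)
    wm[, .WINDOW_CENTER] <- residue
    # anchor columns: kinase-specific pair for substrates, reserved
    # letters for unassigned peptides
    wm[, .WINDOW_CENTER - 3L] <- sample(.NULL_AA, n_pep, replace = TRUE)
    wm[, .WINDOW_CENTER - 2L] <- sample(.NULL_AA, n_pep, replace = TRUE)
    for (k in seq_len(cfg$n_kinases)) {
      rows <- which(assignment == kinase_ids[k])
      wm[rows, .WINDOW_CENTER - 3L] <- combos$a1[k]
      wm[rows, .WINDOW_CENTER - 2L] <- combos$a2[k]
    }
    data.frame(peptide_id = sprintf("pep%05d", seq_len(n_pep)),
               protein_ids = sprintf("PROT%05d", sample.int(n_pep)),
               residue = residue,
               site_position = sample.int(2000L, n_pep, replace = TRUE),
               sequence_window = apply(wm, 1, paste, collapse = ""))
  })

  effects <- numeric(n_pep)
  if (!is.null(cfg$planted_kinases)) {
    for (i in seq_len(nrow(cfg$planted_kinases))) {
      kid <- cfg$planted_kinases$kinase_id[i]
      if (!kid %in% kinase_ids)
        stop_validation("planted kinase not in the simulated library: ", kid)
      effects[assignment == kid & !is.na(assignment)] <-
        cfg$planted_kinases$log2_effect[i]
    }
  }

  gen <- with_seed(substream_seed(cfg$seed, "phospho-intensities"), {
    base <- stats::rnorm(n_pep, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    log2v <- matrix(stats::rnorm(n_pep * n_samp, 0, cfg$within_log2_sd),
                    n_pep, n_samp) + base
    log2v[, is_r] <- log2v[, is_r] + effects
    p_drop <- pmin(pmax(cfg$dropout_baseline -
                          cfg$dropout_shift_per_log2 * log2v, 0), 1)
    dropped <- matrix(stats::runif(n_pep * n_samp), n_pep, n_samp) < p_drop
    vals <- 2^log2v
    vals[dropped] <- 0
    excl_group <- rep(NA_character_, n_pep)
    n_excl <- round(cfg$exclusive_fraction * n_pep)
    if (n_excl > 0) {
      idx <- sample.int(n_pep, n_excl)
      zero_in_resp <- sample(c(TRUE, FALSE), n_excl, replace = TRUE)
      excl_group[idx] <- ifelse(zero_in_resp, "responder", "nonresponder")
      vals[idx[zero_in_resp], is_r] <- 0
      vals[idx[!zero_in_resp], !is_r] <- 0
    }
    list(vals = vals, excl_group = excl_group)
  })

  motifs <- as_motif_library(lapply(seq_len(cfg$n_kinases), function(k) {
    acceptors <- unique(peptides$residue[assignment == kinase_ids[k] &
                                           !is.na(assignment)])
    if (!length(acceptors)) acceptors <- c("S", "T", "Y")
    parse_motif(paste0(combos$a1[k], "-", combos$a2[k], "-X-",
                       paste0("p", acceptors, collapse = "/")),
                kinase_id = kinase_ids[k])
  }))

  truth <- list(planted_kinases = if (is.null(cfg$planted_kinases))
                  data.frame(kinase_id = character(0),
                             log2_effect = numeric(0))
                else cfg$planted_kinases,
                assignment = data.frame(peptide_id = peptides$peptide_id,
                                        kinase_id = assignment),
                exclusive = data.frame(peptide_id = peptides$peptide_id,
                                       zero_group = gen$excl_group)[
                  !is.na(gen$excl_group), , drop = FALSE])

  list(matrix = phospho_matrix(gen$vals, peptides, samples),
       annotations = ann, motifs = motifs, truth = truth)
}

#' Configuration for the synthetic IHC cohort
#'
#' @param n_patients cohort size (>= 8).
#' @param markers marker names; the first marker drives the pCR outcome,
#'   later markers correlate with it.
#' @param pcr_rate_low pCR probability for patients at or below the
#'   driving marker's 75th percentile.
#' @param pcr_rate_upper_quartile pCR probability above that percentile.
#' @param marker_correlation latent correlation between marker H-scores.
#' @param seed integer seed.
#' @return An `ihc_sim_config` list.
#' @export
ihc_sim_config <- function(n_patients = 100L,
                           markers = c("CDK4", "FLNA"),
                           pcr_rate_low = 0.30,
                           pcr_rate_upper_quartile = 0.90,
                           marker_correlation = 0.8,
                           seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), markers = markers,
              pcr_rate_low = pcr_rate_low,
              pcr_rate_upper_quartile = pcr_rate_upper_quartile,
              marker_correlation = marker_correlation,
              seed = as.integer(seed))
  if (cfg$n_patients < 8L) stop_validation("need at least 8 patients")
  for (f in c("pcr_rate_low", "pcr_rate_upper_quartile"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_validation(f, " must be a probability in [0, 1]")
  if (abs(cfg$marker_correlation) > 1)
    stop_validation("marker_correlation must lie in [-1, 1]")
  class(cfg) <- "ihc_sim_config"
  cfg
}

#' Simulate an IHC cohort with a planted upper-quartile/pCR association
#'
#' Latent patient scores are multivariate normal with the configured
#' inter-marker correlation and mapped monotonically to staining area
#' fractions, so H-scores are continuous in `[0, 3]`. The pCR outcome is
#' Bernoulli with probability `pcr_rate_upper_quartile` when the first
#' marker's H-score is above its cohort 75th percentile and
#' `pcr_rate_low` otherwise.
#'
#' @param config an [ihc_sim_config()].
#' @return Long-format data frame: `patient_id`, `marker`, `pct_high`,
#'   `pct_medium`, `pct_low`, `h_score`, `subtype`, `pcr`.
#' @export
simulate_ihc_cohort <- function(config) {
  stopifnot(inherits(config, "ihc_sim_config"))
  cfg <- config
  n <- cfg$n_patients
  m <- length(cfg$markers)
  sigma <- matrix(cfg$marker_correlation, m, m); diag(sigma) <- 1
  with_seed(substream_seed(cfg$seed, "ihc-cohort"), {
    z <- MASS::mvrnorm(n, mu = rep(0, m), Sigma = sigma)
    if (m == 1L) z <- matrix(z, ncol = 1L)
    p <- stats::pnorm(z)
    # stained fraction scales with p; within stained tissue the
    # high/medium/low split follows (p^2, 2p(1-p), (1-p)^2), giving the
    # strictly monotone continuous H-score p * (1 + 2p) in [0, 3]
    pct_high <- 100 * p * p^2
    pct_med <- 100 * p * 2 * p * (1 - p)
    pct_low <- 100 * p * (1 - p)^2
    h <- (3 * pct_high + 2 * pct_med + pct_low) / 100
    cutoff <- stats::quantile(h[, 1], 0.75, type = 7)
    p_pcr <- ifelse(h[, 1] > cutoff, cfg$pcr_rate_upper_quartile,
                    cfg$pcr_rate_low)
    pcr <- stats::runif(n) < p_pcr
    subtype <- sample(c("HR+", "HER2", "TNBC"), n, replace = TRUE,
                      prob = c(0.5, 0.25, 0.25))
    data.frame(patient_id = rep(sprintf("PT%04d", seq_len(n)), m),
               marker = rep(cfg$markers, each = n),
               pct_high = as.vector(pct_high),
               pct_medium = as.vector(pct_med),
               pct_low = as.vector(pct_low),
               h_score = as.vector(h),
               subtype = rep(subtype, m),
               pcr = rep(pcr, m),
               row.names = NULL)
  })
}

#' Simulate pull-down tables with planted bait-specific interactors
#'
#' Background proteins have bait and IgG intensities drawn around a shared
#' log2-normal baseline; planted interactors get the stated log2
#' enrichment added to bait; an optional subset of planted proteins is
#' absent (0) from every IgG replicate.
#'
#' @param n_proteins total proteins (background + planted).
#' @param planted data frame with columns `protein_id` (must look like
#'   the generated `P#####` ids or be new ids) and `bait_log2_enrichment`,
#'   or `NULL`.
#' @param replicates technical replicates per pull-down (>= 1).
#' @param seed integer seed.
#' @param igg_absent character vector of planted protein ids absent from
#'   the IgG control.
#' @param baseline_log2_mean,baseline_log2_sd,noise_log2_sd intensity
#'   model parameters (log2 scale).
#' @param cell_line,bait labels stored on the table.
#' @return A `pulldown_table` (see [pulldown_table()]) with attribute
#'   `truth` naming the planted proteins.
#' @export
simulate_pulldown_tables <- function(n_proteins, planted = NULL,
                                     replicates = 2L, seed = 1L,
                                     igg_absent = character(0),
                                     baseline_log2_mean = 17,
                                     baseline_log2_sd = 2,
                                     noise_log2_sd = 0.35,
                                     cell_line = "SYNTH",
                                     bait = "BAIT") {
  if (replicates < 1L) stop_validation("replicates must be >= 1")
  planted <- if (is.null(planted))
    data.frame(protein_id = character(0), bait_log2_enrichment = numeric(0))
  else as.data.frame(planted)
  if (nrow(planted) &&
      !all(c("protein_id", "bait_log2_enrichment") %in% names(planted)))
    stop_validation("planted needs columns protein_id, bait_log2_enrichment")
  if (nrow(planted) > n_proteins)
    stop_validation("more planted proteins than n_proteins")

  proteins <- sprintf("P%05d", seq_len(n_proteins))
  proteins[seq_len(nrow(planted))] <- planted$protein_id
  enrich <- numeric(n_proteins)
  enrich[seq_len(nrow(planted))] <- planted$bait_log2_enrichment
  if (!all(igg_absent %in% planted$protein_id))
    stop_validation("igg_absent must name planted proteins")

  with_seed(substream_seed(seed, "pulldown"), {
    base <- stats::rnorm(n_proteins, baseline_log2_mean, baseline_log2_sd)
    noise <- function() matrix(stats::rnorm(n_proteins * replicates, 0,
                                            noise_log2_sd),
                               n_proteins, replicates)
    bait_m <- 2^(base + enrich + noise())
    igg_m <- 2^(base + noise())
    igg_m[proteins %in% igg_absent, ] <- 0
    tbl <- pulldown_table(proteins, bait_m, igg_m, cell_line = cell_line,
                          bait_name = bait)
    attr(tbl, "truth") <- list(planted = planted, igg_absent = igg_absent)
    tbl
  })
}

#' Write a simulated phospho dataset to disk in the package's TSV dialects
#'
#' Emits `matrix.tsv`, `annotations.tsv`, `motifs.tsv` and a `truth.json`
#' sidecar documenting the planted effects.
#'
#' @param sim result of [simulate_phospho_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             motifs = file.path(dir, "motifs.tsv"),
             truth = file.path(dir, "truth.json"))
  mat_df <- cbind(sim$matrix$peptides,
                  as.data.frame(sim$matrix$values, check.names = FALSE))
  write_results_table(mat_df, paths[["matrix"]])
  write_results_table(sim$annotations, paths[["annotations"]])
  write_motif_library(sim$motifs, paths[["motifs"]])
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(paths)
}
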