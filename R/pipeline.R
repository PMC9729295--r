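# End-to-end orchestration: differential screen -> KSEA -> optional IHC
# and pull-down stages, with per-stage TSV outputs and a JSON
# reproducibility manifest.

.default_config <- function() {
  list(matrix = NULL, annotations = NULL, motifs = NULL,
       ihc = NULL, ihc_markers = NULL, pulldown = NULL,
       stages = NULL, arm = "all",
       n_perm_diff = 100000L, n_perm_ksea = 1000L,
       fc_threshold_log2 = 4, p_threshold = 10^-2.5,
       peptide_fdr = 0.25, ksea_fdr = 0.20,
       pulldown_log2 = 2, bonferroni_m = 5L,
       seed = NULL, out_dir = NULL)
}

#' Run the full biomarker-discovery screen
#'
#' Executes the configured stages -- differential phosphopeptide analysis,
#' KSEA, IHC association screen, pull-down screen -- reading the input
#' tables named in the config, writing one TSV per stage plus volcano and
#' barcode coordinate files, and a JSON manifest recording the config
#' fingerprint, seed, versions and per-stage row counts. Identical config
#' and seed give byte-identical stage outputs.
#'
#' @param config named list, or path to a YAML file, with fields:
#'   `matrix`, `annotations` (paths; required for the `diff`/`ksea`
#'   stages), `motifs` (path; required for `ksea`), `ihc` (path) and
#'   `ihc_markers`, `pulldown` (path), `stages` (subset of
#'   `c("diff","ksea","ihc","pulldown")`; default: every stage whose
#'   inputs are present), `arm`, `n_perm_diff`, `n_perm_ksea`,
#'   `fc_threshold_log2`, `p_threshold`, `peptide_fdr`, `ksea_fdr`,
#'   `pulldown_log2`, `bonferroni_m`, `seed` (required), `out_dir`
#'   (required).
#' @return Invisibly, the manifest list.
#' @export
run_screen <- function(config) {
  if (is_string(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_validation("config must be a list or YAML path")
  cfg <- utils::modifyList(.default_config(), config)
  if (is.null(cfg$seed))
    stop_validation("config field `seed` is required")
  if (is.null(cfg$out_dir))
    stop_validation("config field `out_dir` is required")
  if (is.null(cfg$stages))
    cfg$stages <- c("diff",
                    if (!is.null(cfg$motifs)) "ksea",
                    if (!is.null(cfg$ihc)) "ihc",
                    if (!is.null(cfg$pulldown)) "pulldown")
  bad <- setdiff(cfg$stages, c("diff", "ksea", "ihc", "pulldown"))
  if (length(bad)) stop_validation("unknown stage(s): ",
                                   paste(bad, collapse = ", "))
  need <- function(field) {
    if (is.null(cfg[[field]]))
      stop_validation("config field `", field, "` is required for the ",
                      "requested stages")
    cfg[[field]]
  }
  if (any(c("diff", "ksea") %in% cfg$stages)) {
    need("matrix"); need("annotations")
  }
  if ("ksea" %in% cfg$stages) need("motifs")
  if ("ihc" %in% cfg$stages) need("ihc")
  if ("pulldown" %in% cfg$stages) need("pulldown")
  stopifnot(cfg$fc_threshold_log2 > 0, cfg$p_threshold > 0,
            cfg$peptide_fdr > 0, cfg$ksea_fdr > 0, cfg$pulldown_log2 > 0)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    tmp <- paste0(path, ".partial")
    write_results_table(df, tmp)
    file.rename(tmp, path)
    path
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE))
  }

  mat <- ann <- NULL
  if (any(c("diff", "ksea") %in% cfg$stages)) {
    mat <- read_intensity_table(cfg$matrix)
    ann <- read_sample_annotations(cfg$annotations)
  }

  if ("diff" %in% cfg$stages) {
    run_stage("diff", {
      fit <- phospho_diff(mat, ann, arm = cfg$arm,
                          n_perm = cfg$n_perm_diff, seed = cfg$seed,
                          fc_threshold_log2 = cfg$fc_threshold_log2,
                          p_threshold = cfg$p_threshold,
                          fdr_threshold = cfg$peptide_fdr)
      emit(fit$results, "differential.tsv")
      emit(fit$results[, c("peptide_id", "volcano_x", "volcano_y",
                           "cloud", "is_hit")], "volcano.tsv")
      counts$diff <- nrow(fit$results)
      message("diff: ", nrow(fit$results), " peptides tested, ",
              sum(fit$results$is_hit), " hits")
    })
  }
  if ("ksea" %in% cfg$stages) {
    run_stage("ksea", {
      motifs <- read_motif_library(cfg$motifs)
      fit <- ksea(mat, ann, motifs, arm = cfg$arm,
                  n_perm = cfg$n_perm_ksea, seed = cfg$seed,
                  fdr_threshold = cfg$ksea_fdr)
      emit(fit$results, "ksea.tsv")
      emit(ksea_barcode(fit), "ksea_barcode.tsv")
      counts$ksea <- nrow(fit$results)
      message("ksea: ", nrow(fit$results), " kinase sets, ",
              sum(fit$results$significant), " significant")
    })
  }
  if ("ihc" %in% cfg$stages) {
    run_stage("ihc", {
      sep <- if (grepl("\\.csv$", cfg$ihc)) "," else "\t"
      rec <- utils::read.table(cfg$ihc, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE)
      scr <- ihc_screen(rec, markers = cfg$ihc_markers,
                        m_comparisons = cfg$bonferroni_m)
      emit(as.data.frame(scr), "ihc_associations.tsv")
      counts$ihc <- nrow(scr)
      message("ihc: ", nrow(scr), " markers screened")
    })
  }
  if ("pulldown" %in% cfg$stages) {
    run_stage("pulldown", {
      tbl <- read_pulldown_table(cfg$pulldown)
      scr <- pulldown_screen(tbl, log2_threshold = cfg$pulldown_log2)
      emit(scr$points, "pulldown_points.tsv")
      counts$pulldown <- nrow(scr$points)
      message("pulldown: ", nrow(scr$points), " proteins, ",
              sum(scr$points$is_candidate), " candidates")
    })
  }

  cfg_json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                               null = "null", digits = NA)
  manifest <- list(package = "phosphoscreen",
                   version = as.character(utils::packageVersion("phosphoscreen")),
                   r_version = R.version.string,
                   seed = cfg$seed,
                   config = cfg,
                   config_hash = config_hash(as.character(cfg_json)),
                   stages = cfg$stages,
                   rows = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  invisible(manifest)
}
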