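## End-to-end orchestration: simulate or load inputs, run every analysis
## stage in order, write all tabular/JSON outputs, and record a manifest
## with seeds, parameters, and file checksums so a run can be reproduced
## bit-identically.

#' Pipeline run configuration
#'
#' Inputs may be file paths (cohort CSV / cell-type score CSV) or generator
#' configurations; exactly one of each pair is used. The deconvolution
#' stage uses the chemosensitive-vs-chemoresistant dichotomy, the screening
#' and modeling stages the pCR-vs-RD dichotomy.
#'
#' @param cohort Path to a cohort CSV, or a [cohort_config()].
#' @param celltype_scores Path to a score CSV, a [celltype_config()], or
#'   `NULL` to skip the deconvolution stage.
#' @param out_dir Output directory (created if needed).
#' @param top_k Screened features carried into the model (default 5).
#' @param epsilon Denominator guard for feature computation.
#' @param n_boot Bootstrap iterations (default 1000).
#' @param n_permutations Label permutations (default 1000).
#' @param model Model settings, a [model_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `nact_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       celltype_scores = celltype_config(),
                       out_dir = tempfile("nactsig_run_"),
                       top_k = 5L, epsilon = 0.01,
                       n_boot = 1000L, n_permutations = 1000L,
                       model = model_config(),
                       seed = 1L) {
  structure(list(cohort = cohort, celltype_scores = celltype_scores,
                 out_dir = out_dir, top_k = as.integer(top_k),
                 epsilon = epsilon, n_boot = as.integer(n_boot),
                 n_permutations = as.integer(n_permutations),
                 model = model, seed = as.integer(seed)),
            class = "nact_run_config")
}

## Deterministic stage seeds derived from the master seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  (seed * 1000L + stage) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Stages, in order: simulate or load the cohort and cell-type scores;
#' volcano classification of cell-type enrichment (sensitive vs resistant);
#' composite feature computation; univariate screening; RCB-stratified
#' correlation networks with bootstrap CIs; Random Forest validation of the
#' top screened features plus phenotype dummies (stratified CV, bootstrap,
#' permutation test, Gini importance, diagnostics); and the clinical-only
#' baseline comparison under the identical fold assignment. Every output
#' file is listed in `manifest.json` with its MD5 checksum, alongside all
#' seeds and parameters.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "nact_run_config"))
  if (is.character(config$cohort) && !file.exists(config$cohort)) {
    abort_nact("nactsig_io_error",
               sprintf("cohort file not found: '%s'", config$cohort))
  }
  if (is.character(config$celltype_scores) &&
      !file.exists(config$celltype_scores)) {
    abort_nact("nactsig_io_error",
               sprintf("score file not found: '%s'", config$celltype_scores))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  outputs <- character()
  emit <- function(f) outputs <<- c(outputs, path(f))

  ## -- stage 1: inputs ----------------------------------------------------
  cohort <- if (is.character(config$cohort)) {
    read_cohort_csv(config$cohort)
  } else {
    cfg <- config$cohort
    cfg$seed <- cfg$seed %||% stage_seed(config$seed, 1L)
    generate_cohort(cfg)
  }
  write_cohort_csv(cohort, path("cohort.csv")); emit("cohort.csv")
  summ <- summarize_cohort(cohort)
  cohort_summary_json(summ, path("cohort_summary.json"))
  emit("cohort_summary.json")

  volcano <- NULL
  if (!is.null(config$celltype_scores)) {
    scores <- if (is.character(config$celltype_scores)) {
      read_celltype_csv(config$celltype_scores)
    } else {
      cfg <- config$celltype_scores
      cfg$seed <- cfg$seed %||% stage_seed(config$seed, 2L)
      generate_celltype_scores(cfg)
    }
    write_celltype_csv(scores, path("celltype_scores.csv"))
    emit("celltype_scores.csv")
    ## -- stage 2: deconvolution group stats (sensitive vs resistant) ------
    volcano <- volcano_table(scores)
    write.csv(as.data.frame(volcano), path("volcano.csv"), row.names = FALSE)
    emit("volcano.csv")
  }

  ## -- stage 3: composite features ----------------------------------------
  defs <- enumerate_features()
  fm <- compute_features(cohort, defs, epsilon = config$epsilon)
  write.csv(as.data.frame(fm), path("features.csv"), row.names = FALSE)
  emit("features.csv")

  ## -- stage 4: univariate screen (pCR vs RD) ------------------------------
  labels <- derive_labels(cohort, "pcr_vs_rd")
  screen <- screen_features(fm, labels, top_k = config$top_k)
  write_screen_csv(screen, path("screen.csv"))
  emit("screen.csv")

  ## -- stage 5: stratified correlation networks ----------------------------
  corr <- stratified_correlations(cohort, n_resamples = config$n_boot,
                                  seed = stage_seed(config$seed, 5L))
  write.csv(as.data.frame(corr), path("correlations.csv"), row.names = FALSE)
  emit("correlations.csv")

  ## -- stage 6: model validation -------------------------------------------
  top_features <- screen$feature[seq_len(config$top_k)]
  dummies <- encode_phenotype_dummies(cohort)
  x_main <- dplyr::bind_cols(as_tibble(as.data.frame(fm)[top_features],
                                       .name_repair = "minimal"), dummies)
  mcfg <- config$model
  mcfg$seed <- mcfg$seed %||% stage_seed(config$seed, 6L)
  main_cv <- stratified_cv_oof(x_main, labels, mcfg)
  main_boot <- bootstrap_oof_auc(main_cv$oof_probabilities, labels,
                                 n_iterations = config$n_boot,
                                 seed = stage_seed(config$seed, 7L))
  perm <- permutation_test(x_main, labels, mcfg,
                           n_permutations = config$n_permutations,
                           seed = stage_seed(config$seed, 8L),
                           observed_cv = main_cv)
  diag <- diagnostic_metrics(main_cv$oof_probabilities, labels,
                             threshold = mcfg$probability_threshold)
  imp <- gini_importance(x_main, labels, mcfg)
  write.csv(as.data.frame(imp), path("importance.csv"), row.names = FALSE)
  emit("importance.csv")
  oof <- tibble(patient_id = cohort$patient_id,
                fold = main_cv$fold_assignment,
                probability = main_cv$oof_probabilities,
                label = labels)
  write.csv(as.data.frame(oof), path("oof_predictions.csv"), row.names = FALSE)
  emit("oof_predictions.csv")

  ## -- stage 7: clinical-only baseline under identical folds ---------------
  base_cv <- stratified_cv_oof(dummies, labels, mcfg,
                               fold_assignment = main_cv$fold_assignment)
  base_boot <- bootstrap_oof_auc(base_cv$oof_probabilities, labels,
                                 n_iterations = config$n_boot,
                                 seed = stage_seed(config$seed, 9L))
  comp <- compare_models(main_cv, base_cv, main_boot, base_boot)

  metrics <- list(
    pooled_oof_auc = main_cv$pooled_oof_auc,
    mean_fold_auc = main_cv$mean_fold_auc,
    per_fold_auc = main_cv$per_fold_auc,
    mean_average_precision = main_cv$mean_ap,
    bootstrap = main_boot[c("n_iterations", "mean_auc", "median_auc",
                            "ci_low", "ci_high")],
    permutation = perm[c("observed_auc", "mean_null_auc", "p_one_sided",
                         "n_permutations")],
    diagnostics = unclass(diag)
  )
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA),
             path("metrics.json"))
  emit("metrics.json")
  comparison <- list(
    delta_pooled_auc = comp$delta_pooled_auc,
    delta_mean_bootstrap = comp$delta_mean_bootstrap,
    delta_median_bootstrap = comp$delta_median_bootstrap,
    main_pooled_auc = comp$main_pooled_auc,
    baseline_pooled_auc = comp$baseline_pooled_auc,
    baseline_bootstrap = base_boot[c("n_iterations", "mean_auc", "median_auc",
                                     "ci_low", "ci_high")]
  )
  writeLines(jsonlite::toJSON(comparison, auto_unbox = TRUE, digits = NA),
             path("comparison.json"))
  emit("comparison.json")

  manifest <- list(
    package = "nactsig",
    seed = config$seed,
    parameters = list(top_k = config$top_k, epsilon = config$epsilon,
                      n_boot = config$n_boot,
                      n_permutations = config$n_permutations,
                      n_trees = mcfg$n_trees, n_folds = mcfg$n_folds,
                      probability_threshold = mcfg$probability_threshold),
    stage_seeds = setNames(
      as.list(stage_seed(config$seed, c(1L, 2L, 5L, 6L, 7L, 8L, 9L))),
      c("cohort", "celltype", "correlations", "model", "bootstrap",
        "permutation", "baseline_bootstrap")),
    files = lapply(setNames(outputs, basename(outputs)), function(f) {
      list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    })
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             path("manifest.json"))

  invisible(list(cohort = cohort, summary = summ, volcano = volcano,
                 features = fm, screen = screen, correlations = corr,
                 main_cv = main_cv, main_bootstrap = main_boot,
                 permutation = perm, diagnostics = diag, importance = imp,
                 baseline_cv = base_cv, baseline_bootstrap = base_boot,
                 comparison = comp, manifest = manifest))
}
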