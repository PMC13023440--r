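## Multivariate validation harness: stratified cross-validation with pooled
## out-of-fold (OOF) predictions from a Random Forest, bootstrap and Monte
## Carlo permutation inference on the pooled OOF AUC, Gini importances,
## diagnostic metrics, and the clinical-baseline comparison. The tree
## learner itself is ranger; all inference machinery around it (fold
## construction, pooling, bootstrap, permutation, deltas) lives here.

#' Random Forest validation configuration
#'
#' @param n_trees Number of trees (default 100).
#' @param n_folds Stratified CV folds (default 5).
#' @param probability_threshold OOF probability cutoff for the confusion
#'   matrix (default 0.5).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `nact_model_config`.
#' @export
model_config <- function(n_trees = 100L, n_folds = 5L,
                         probability_threshold = 0.5, seed = NULL) {
  if (n_folds < 2) abort_nact("nactsig_config_error", "n_folds must be >= 2")
  structure(list(n_trees = as.integer(n_trees), n_folds = as.integer(n_folds),
                 probability_threshold = probability_threshold, seed = seed),
            class = "nact_model_config")
}

#' Stratified fold assignment
#'
#' Shuffles each class separately and deals its members into folds
#' round-robin, so every fold's class-1 count is within one patient of the
#' proportional share.
#'
#' @param labels 0/1 vector.
#' @param n_folds Number of folds.
#' @return Integer vector of fold ids in 1..n_folds.
#' @export
make_stratified_folds <- function(labels, n_folds) {
  labels <- as.integer(labels)
  if (min(sum(labels == 0), sum(labels == 1)) < n_folds) {
    abort_nact("nactsig_stratification_error",
               "each class must have at least n_folds members")
  }
  folds <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

## Balanced class weights (w_c = n / (2 n_c)) on the splitting rule.
fit_rf <- function(x, y01, n_trees, seed, importance = "none") {
  y <- factor(y01, levels = c(0, 1))
  tab <- table(y)
  ranger::ranger(
    x = x, y = y,
    num.trees = n_trees,
    probability = TRUE,
    class.weights = as.numeric(sum(tab) / (2 * tab)),
    importance = importance,
    seed = seed,
    num.threads = 1
  )
}

predict_rf <- function(fit, x) {
  predict(fit, data = x, num.threads = 1)$predictions[, "1"]
}

## Average precision by threshold steps over the observed scores
## (step integral of the precision-recall curve).
average_precision <- function(scores, labels) {
  labels <- as.integer(labels)
  ths <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  rec_prev <- 0
  ap <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / n_pos
    ap <- ap + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  ap
}

#' Stratified cross-validation with pooled out-of-fold predictions
#'
#' Trains a Random Forest (probability forest, balanced class weights) on
#' each fold's complement and records the out-of-fold probability of class 1
#' (residual disease) for every patient exactly once. Reports per-fold AUC
#' and average precision, their means, and the pooled OOF AUC computed on
#' the concatenated OOF predictions.
#'
#' @param features Data frame of predictors (numeric columns).
#' @param labels 0/1 outcome vector (1 = residual disease).
#' @param config A [model_config()].
#' @param fold_assignment Optional precomputed fold ids; drawn freshly
#'   (stratified) when `NULL`. Every fold must contain both classes.
#' @return A list of class `nact_cv_result` with `oof_probabilities`,
#'   `fold_assignment`, `per_fold_auc`, `mean_fold_auc`, `pooled_oof_auc`,
#'   `per_fold_ap`, `mean_ap`, `labels`, `config`.
#' @export
stratified_cv_oof <- function(features, labels, config = model_config(),
                              fold_assignment = NULL) {
  labels <- as.integer(labels)
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels))
  with_seed_(config$seed, {
    if (is.null(fold_assignment)) {
      fold_assignment <- make_stratified_folds(labels, config$n_folds)
    }
    if (any(vapply(seq_len(config$n_folds),
                   function(f) length(unique(labels[fold_assignment == f])) < 2,
                   TRUE))) {
      abort_nact("nactsig_stratification_error",
                 "every fold must contain both classes")
    }
    oof <- rep(NA_real_, length(labels))
    per_fold_auc <- numeric(config$n_folds)
    per_fold_ap <- numeric(config$n_folds)
    for (f in seq_len(config$n_folds)) {
      test <- fold_assignment == f
      fit <- fit_rf(features[!test, , drop = FALSE], labels[!test],
                    config$n_trees, seed = sample.int(.Machine$integer.max, 1))
      oof[test] <- predict_rf(fit, features[test, , drop = FALSE])
      per_fold_auc[f] <- roc_auc(oof[test], labels[test])
      per_fold_ap[f] <- average_precision(oof[test], labels[test])
    }
    structure(list(
      oof_probabilities = oof,
      fold_assignment = fold_assignment,
      per_fold_auc = per_fold_auc,
      mean_fold_auc = mean(per_fold_auc),
      pooled_oof_auc = roc_auc(oof, labels),
      per_fold_ap = per_fold_ap,
      mean_ap = mean(per_fold_ap),
      labels = labels,
      config = config
    ), class = "nact_cv_result")
  })
}

#' Bootstrap the pooled out-of-fold AUC
#'
#' Resamples (OOF probability, label) pairs with replacement; resamples
#' containing a single class have no defined AUC and are redrawn so that
#' exactly `n_iterations` valid AUCs enter the mean, median, and 2.5/97.5
#' percentile interval.
#'
#' @param oof_probabilities OOF probabilities from [stratified_cv_oof()].
#' @param labels Matching 0/1 labels.
#' @param n_iterations Valid bootstrap iterations (default 1000).
#' @param seed Integer seed or `NULL`.
#' @param max_redraw_factor Retry budget multiple.
#' @return A list of class `nact_bootstrap_summary` with `n_iterations`,
#'   `mean_auc`, `median_auc`, `ci_low`, `ci_high`, `aucs`.
#' @export
bootstrap_oof_auc <- function(oof_probabilities, labels, n_iterations = 1000L,
                              seed = NULL, max_redraw_factor = 100) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    abort_nact("nactsig_input_error", "both classes must be present")
  }
  n <- length(labels)
  with_seed_(seed, {
    aucs <- numeric(n_iterations)
    kept <- 0L
    redraws <- 0L
    while (kept < n_iterations) {
      idx <- sample.int(n, n, replace = TRUE)
      li <- labels[idx]
      if (all(li == li[1])) {
        redraws <- redraws + 1L
        if (redraws > max_redraw_factor * n_iterations) {
          abort_nact("nactsig_input_error",
                     "bootstrap retry budget exhausted (degenerate labels)")
        }
        next
      }
      kept <- kept + 1L
      aucs[kept] <- roc_auc(oof_probabilities[idx], li)
    }
    q <- unname(quantile(aucs, c(0.025, 0.975)))
    structure(list(n_iterations = n_iterations, mean_auc = mean(aucs),
                   median_auc = median(aucs), ci_low = q[1], ci_high = q[2],
                   aucs = aucs),
              class = "nact_bootstrap_summary")
  })
}

#' One-sided Monte Carlo permutation test of the pooled OOF AUC
#'
#' For each permutation the class labels are shuffled and the full
#' stratified cross-validation pipeline is re-run — including drawing a
#' fresh stratified fold partition for the permuted labels, so every null
#' replicate goes through exactly the procedure the observed statistic went
#' through; the null statistic is the pooled OOF AUC. (Reusing the observed
#' partition verbatim makes per-fold class imbalance of the permuted labels
#' anti-correlate between training and test folds and biases the null mean
#' of the pooled AUC visibly below 0.5.) The p-value uses the add-one
#' convention
#' p = (1 + #\{null >= observed\}) / (1 + n_permutations), bounded below by
#' 1/(n_permutations + 1).
#'
#' @inheritParams stratified_cv_oof
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed or `NULL` (controls both the observed CV draw
#'   and the permutations).
#' @param observed_cv Optional precomputed `nact_cv_result` for the
#'   unpermuted labels (avoids refitting).
#' @return A list of class `nact_permutation_result` with `observed_auc`,
#'   `null_auc_distribution`, `mean_null_auc`, `p_one_sided`,
#'   `n_permutations`.
#' @export
permutation_test <- function(features, labels, config = model_config(),
                             n_permutations = 1000L, seed = NULL,
                             observed_cv = NULL) {
  labels <- as.integer(labels)
  with_seed_(seed, {
    if (is.null(observed_cv)) {
      observed_cv <- stratified_cv_oof(features, labels, config)
    }
    null_auc <- numeric(n_permutations)
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      cv <- stratified_cv_oof(features, perm, config)
      null_auc[b] <- cv$pooled_oof_auc
    }
    structure(list(
      observed_auc = observed_cv$pooled_oof_auc,
      null_auc_distribution = null_auc,
      mean_null_auc = mean(null_auc),
      p_one_sided = (1 + sum(null_auc >= observed_cv$pooled_oof_auc)) /
        (1 + n_permutations),
      n_permutations = n_permutations
    ), class = "nact_permutation_result")
  })
}

#' Diagnostic metrics from out-of-fold predictions
#'
#' Confusion counts with residual disease (label 1) as the positive class
#' and "predicted RD" meaning OOF probability >= threshold; sensitivity,
#' specificity, PPV, NPV, and accuracy as percentages (full precision;
#' round at the reporting edge).
#'
#' @param oof_probabilities OOF probabilities.
#' @param labels 0/1 labels.
#' @param threshold Probability cutoff (default 0.5).
#' @return A list of class `nact_diagnostics` with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
diagnostic_metrics <- function(oof_probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- oof_probabilities >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn),
    accuracy = 100 * (tp + tn) / length(labels)
  ), class = "nact_diagnostics")
}

#' Gini feature importance from the full-data model
#'
#' Fits the Random Forest on the complete dataset and reports mean decrease
#' in Gini impurity, normalized to sum to one and ranked descending.
#'
#' @inheritParams stratified_cv_oof
#' @return A tibble with `feature`, `importance`, `rank`.
#' @export
gini_importance <- function(features, labels, config = model_config()) {
  labels <- as.integer(labels)
  features <- as.data.frame(features)
  with_seed_(config$seed, {
    fit <- fit_rf(features, labels, config$n_trees,
                  seed = sample.int(.Machine$integer.max, 1),
                  importance = "impurity")
    imp <- fit$variable.importance
    imp <- imp / sum(imp)
    out <- tibble(feature = names(imp), importance = unname(imp))
    out <- out[order(-out$importance), ]
    out$rank <- seq_len(nrow(out))
    out
  })
}

#' Compare the main model against the clinical baseline
#'
#' Both models must have been evaluated on the same patients under the same
#' fold assignment ("identical cross-validation conditions"); otherwise a
#' comparison error is raised. Deltas are main minus baseline: the pooled
#' OOF AUC point estimate and the means/medians of the two bootstrap AUC
#' distributions.
#'
#' @param main_cv,baseline_cv `nact_cv_result` objects.
#' @param main_bootstrap,baseline_bootstrap Matching
#'   `nact_bootstrap_summary` objects.
#' @return A list of class `nact_model_comparison` with the three deltas and
#'   both bootstrap summaries.
#' @export
compare_models <- function(main_cv, baseline_cv,
                           main_bootstrap, baseline_bootstrap) {
  if (!identical(main_cv$fold_assignment, baseline_cv$fold_assignment) ||
      !identical(main_cv$labels, baseline_cv$labels)) {
    abort_nact("nactsig_comparison_error",
               "models must share fold assignment and labels")
  }
  structure(list(
    delta_pooled_auc = main_cv$pooled_oof_auc - baseline_cv$pooled_oof_auc,
    delta_mean_bootstrap = main_bootstrap$mean_auc - baseline_bootstrap$mean_auc,
    delta_median_bootstrap = main_bootstrap$median_auc -
      baseline_bootstrap$median_auc,
    main_pooled_auc = main_cv$pooled_oof_auc,
    baseline_pooled_auc = baseline_cv$pooled_oof_auc,
    main_bootstrap = main_bootstrap,
    baseline_bootstrap = baseline_bootstrap
  ), class = "nact_model_comparison")
}

#' Phenotype dummy encoding
#'
#' One indicator column per non-reference phenotype (schema order), with
#' reference-phenotype rows all zero.
#'
#' @param cohort A cohort tibble.
#' @param reference_category Reference phenotype (default HER2).
#' @return A tibble of 0/1 indicator columns aligned to cohort rows.
#' @export
encode_phenotype_dummies <- function(cohort, reference_category = "HER2") {
  if (!reference_category %in% PHENOTYPES) {
    abort_nact("nactsig_config_error",
               sprintf("unknown reference phenotype '%s'", reference_category))
  }
  keep <- setdiff(PHENOTYPES, reference_category)
  out <- lapply(keep, function(ph) as.integer(cohort$phenotype == ph))
  names(out) <- keep
  as_tibble(out)
}
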