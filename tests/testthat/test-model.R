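make_xy <- function(n = 57, n_pos = 37, p = 5, seed = 1) {
  set.seed(seed)
  list(x = as.data.frame(matrix(rnorm(n * p), n,
                                dimnames = list(NULL, paste0("f", 1:p)))),
       y = sample(rep(c(0L, 1L), c(n - n_pos, n_pos))))
}

test_that("phenotype dummies use the reference-category encoding", {
  co <- tiny_cohort(rcb = c("0", "I", "II", "III"),
                    phenotype = c("LuminalA", "LuminalB", "HER2", "TNBC"))
  d <- encode_phenotype_dummies(co)
  expect_identical(names(d), c("LuminalA", "LuminalB", "TNBC"))
  expect_identical(unlist(d[3, ], use.names = FALSE), c(0L, 0L, 0L))  # HER2 row
  expect_identical(diag(as.matrix(d[c(1, 2, 4), ])), c(1L, 1L, 1L))

  tn <- tiny_cohort(rcb = c("0", "I"), phenotype = c("TNBC", "TNBC"))
  dt <- encode_phenotype_dummies(tn)
  expect_true(all(dt$TNBC == 1) && all(dt$LuminalA == 0) && all(dt$LuminalB == 0))

  expect_error(encode_phenotype_dummies(co, "Basal"),
               class = "nactsig_config_error")
})

test_that("stratified folds keep class ratios within one sample", {
  set.seed(2)
  labels <- rep(c(0L, 1L), c(20, 37))
  for (i in 1:20) {
    folds <- make_stratified_folds(labels, 5)
    expect_identical(sort(unique(folds)), 1:5)
    for (f in 1:5) {
      expect_lte(abs(sum(labels[folds == f]) - 37 / 5), 1)
      expect_lte(abs(sum(labels[folds == f] == 0) - 20 / 5), 1)
    }
  }
  expect_error(make_stratified_folds(rep(c(0L, 1L), c(3, 30)), 5),
               class = "nactsig_stratification_error")
})

test_that("a leaked label feature yields pooled OOF AUC of 1", {
  d <- make_xy(seed = 3)
  d$x$leak <- d$y
  cv <- stratified_cv_oof(d$x, d$y, model_config(seed = 7))
  expect_equal(cv$pooled_oof_auc, 1)
  expect_true(all(!is.na(cv$oof_probabilities)))
})

test_that("cross-validation is deterministic and predicts each patient once", {
  d <- make_xy(seed = 4)
  cv1 <- stratified_cv_oof(d$x, d$y, model_config(seed = 11))
  cv2 <- stratified_cv_oof(d$x, d$y, model_config(seed = 11))
  expect_identical(cv1$oof_probabilities, cv2$oof_probabilities)
  expect_identical(cv1$fold_assignment, cv2$fold_assignment)
  expect_false(anyNA(cv1$oof_probabilities))
  ## pooled AUC is a symmetric function of the pooled predictions
  perm <- sample(length(d$y))
  expect_equal(roc_auc(cv1$oof_probabilities[perm], d$y[perm]),
               cv1$pooled_oof_auc)
})

test_that("pure-noise features give chance-level pooled AUC on average", {
  aucs <- vapply(1:50, function(s) {
    d <- make_xy(seed = 600 + s)
    stratified_cv_oof(d$x, d$y, model_config(seed = s))$pooled_oof_auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("bootstrap of OOF predictions summarizes the AUC distribution", {
  labels <- rep(c(0L, 1L), c(20, 37))
  perfect <- as.numeric(labels)
  bs <- bootstrap_oof_auc(perfect, labels, n_iterations = 200, seed = 5)
  expect_equal(bs$mean_auc, 1)
  expect_equal(bs$median_auc, 1)
  expect_equal(c(bs$ci_low, bs$ci_high), c(1, 1))

  noisy <- perfect * 0.5 + runif(57)
  b1 <- bootstrap_oof_auc(noisy, labels, n_iterations = 200, seed = 9)
  b2 <- bootstrap_oof_auc(noisy, labels, n_iterations = 200, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$median_auc && b1$median_auc <= b1$ci_high)
  expect_identical(length(b1$aucs), 200L)
})

test_that("permutation p hits the floor for a strong signal", {
  d <- make_xy(seed = 6)
  d$x$leak <- d$y + rnorm(57, 0, 0.1)
  pr <- permutation_test(d$x, d$y, model_config(seed = 13),
                         n_permutations = 99, seed = 17)
  expect_equal(pr$p_one_sided, 1 / 100)
  expect_identical(length(pr$null_auc_distribution), 99L)
  expect_lt(abs(pr$mean_null_auc - 0.5), 0.1)
})

test_that("diagnostic metrics recompute from confusion counts", {
  ## the printed OOF confusion matrix: 24/37 RD and 12/20 pCR correct
  labels <- rep(c(1L, 1L, 0L, 0L), c(24, 13, 12, 8))
  probs <- rep(c(0.9, 0.1, 0.1, 0.9), c(24, 13, 12, 8))
  dm <- diagnostic_metrics(probs, labels, threshold = 0.5)
  expect_identical(c(dm$tp, dm$fn, dm$tn, dm$fp), c(24L, 13L, 12L, 8L))
  expect_equal(round(dm$sensitivity, 1), 64.9)
  expect_equal(round(dm$specificity, 1), 60.0)
  expect_equal(round(dm$ppv, 1), 75.0)
  expect_equal(round(dm$npv, 1), 48.0)
  expect_equal(round(dm$accuracy, 1), 63.2)
  expect_identical(dm$tp + dm$fp + dm$tn + dm$fn, length(labels))

  perfect <- diagnostic_metrics(as.numeric(labels), labels)
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv, perfect$accuracy), rep(100, 5))

  all_pos <- diagnostic_metrics(rep(1, length(labels)), labels)
  expect_equal(all_pos$sensitivity, 100)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$ppv, 100 * mean(labels))
})

test_that("Gini importances are normalized and expose a leaked feature", {
  d <- make_xy(seed = 8)
  d$x$leak <- d$y
  imp <- gini_importance(d$x, d$y, model_config(seed = 19))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-9)
  expect_identical(imp$feature[1], "leak")
  expect_gt(imp$importance[1], 0.5)
  expect_identical(imp$rank, seq_len(nrow(imp)))
})

test_that("model comparison deltas recompute and identity gives zero", {
  d <- make_xy(seed = 10)
  cfg <- model_config(seed = 23)
  cv <- stratified_cv_oof(d$x, d$y, cfg)
  bs <- bootstrap_oof_auc(cv$oof_probabilities, d$y, 200, seed = 29)
  same <- compare_models(cv, cv, bs, bs)
  expect_equal(same$delta_pooled_auc, 0)
  expect_equal(same$delta_mean_bootstrap, 0)
  expect_equal(same$delta_median_bootstrap, 0)

  ## deltas are plain differences of the component summaries
  fake <- function(mean_, median_) {
    structure(list(mean_auc = mean_, median_auc = median_),
              class = "nact_bootstrap_summary")
  }
  cmp <- compare_models(cv, cv, fake(0.682, 0.686), fake(0.560, 0.560))
  expect_equal(cmp$delta_mean_bootstrap, 0.122)
  expect_equal(cmp$delta_median_bootstrap, 0.126)

  other <- stratified_cv_oof(d$x, d$y, model_config(seed = 31))
  expect_error(compare_models(cv, other, bs, bs),
               class = "nactsig_comparison_error")
})
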