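test_that("AUC matches pair-counting examples and edge cases", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 10, 11), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(3, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "nactsig_input_error")
})

test_that("AUC agrees with brute-force pair counting and Mann-Whitney U", {
  set.seed(19)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- sample(seq_len(8), n, replace = TRUE)
    a <- roc_auc(scores, labels)
    expect_equal(a, brute_force_auc(scores, labels))
    ## cross-module: AUC = U / (n1 n0) with the positive class as first group
    u <- mann_whitney_rb(scores[labels == 1], scores[labels == 0])$U
    expect_equal(a, u / (sum(labels == 1) * sum(labels == 0)))
  }
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(29)
  scores <- rnorm(30)
  labels <- rbinom(30, 1, 0.5)
  labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
  expect_equal(roc_auc(-scores, labels), 1 - a)
})

test_that("Youden cutoff maximizes J with low tie-break", {
  yc <- youden_cutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(yc$threshold, 0.35)
  expect_equal(yc$youden_j, 0.5)

  sep <- youden_cutoff(c(1, 2, 5, 6), c(0, 0, 1, 1))
  expect_equal(sep$threshold, 5)  # smallest positive-class score
  expect_equal(sep$youden_j, 1)

  flat <- youden_cutoff(rep(2, 5), c(0, 0, 1, 1, 1))
  expect_equal(flat$youden_j, 0)
})

test_that("Youden cutoff agrees with the exhaustive-scan oracle", {
  set.seed(37)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.6))
    scores <- round(rnorm(n), 1)
    got <- youden_cutoff(scores, labels)
    want <- brute_force_youden(scores, labels)
    expect_equal(got$youden_j, want$youden_j)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("2x2 odds ratio, Woolf CI, and Fisher p follow the stated rules", {
  ## table a=6 (high RD), b=2 (high pCR), c=3 (low RD), d=9 (low pCR)
  scores <- c(rep(1, 6), rep(1, 2), rep(0, 3), rep(0, 9))
  labels <- c(rep(1, 6), rep(0, 2), rep(1, 3), rep(0, 9))
  dt <- dichotomize_and_test(scores, labels, 0.5)
  expect_equal(unname(dt$table["high", ]), c(6, 2))
  expect_equal(dt$odds_ratio, 9)
  expect_equal(dt$p_raw, brute_force_fisher_p(dt$table))
  expect_true(dt$ci_low <= dt$odds_ratio && dt$odds_ratio <= dt$ci_high)

  ## no association
  scores <- rep(c(1, 0), each = 10)
  labels <- rep(c(1, 0, 1, 0), each = 5)
  flat <- dichotomize_and_test(scores, labels, 0.5)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_raw, 1)

  ## zero cell: Haldane-Anscombe on all cells
  scores <- c(rep(1, 5), rep(0, 10))
  labels <- c(rep(1, 5), rep(1, 2), rep(0, 8))
  ha <- dichotomize_and_test(scores, labels, 0.5)
  expect_equal(ha$odds_ratio, (5.5 * 8.5) / (0.5 * 2.5))
  expect_equal(round(ha$odds_ratio, 1), 37.4)

  ## degenerate margin: flagged with p = 1
  deg <- dichotomize_and_test(rep(1, 10), rep(c(0, 1), 5), 0.5)
  expect_true(deg$degenerate)
  expect_equal(deg$p_raw, 1)
  expect_true(is.na(deg$odds_ratio))
})

test_that("Fisher p agrees with hypergeometric enumeration on random tables", {
  set.seed(43)
  for (i in 1:50) {
    labels <- c(0, 1, rbinom(18, 1, 0.6))
    scores <- runif(20)
    t0 <- quantile(scores, runif(1, 0.2, 0.8))
    dt <- dichotomize_and_test(scores, labels, t0)
    if (!dt$degenerate) {
      expect_equal(dt$p_raw, brute_force_fisher_p(dt$table))
    }
  }
})

test_that("screening ranks by AUC and restricts BH to the top family", {
  co <- generate_cohort(cohort_config(seed = 3))
  labels <- derive_labels(co, "pcr_vs_rd")
  fm <- compute_features(co)
  ## a perfectly separating feature must take rank 1 with AUC 1
  fm$oracle <- labels + runif(nrow(fm), 0, 0.5)
  sc <- screen_features(fm, labels, top_k = 5)
  expect_identical(sc$feature[1], "oracle")
  expect_equal(sc$auc[1], 1)
  expect_identical(sc$rank, seq_len(nrow(sc)))
  expect_true(all(diff(sc$auc) <= 1e-12))
  ## BH family is the top 5 only
  expect_identical(sum(!is.na(sc$p_adj)), 5L)
  expect_equal(sc$p_adj[1:5], bh_adjust(sc$p_raw[1:5]))
  ## 2x2 margins equal the class counts
  expect_true(all(sc$n_high_rd + sc$n_low_rd == sum(labels == 1)))
  expect_true(all(sc$n_high_pcr + sc$n_low_pcr == sum(labels == 0)))

  expect_error(screen_features(fm[, 1:4], labels, top_k = 10),
               class = "nactsig_config_error")
})
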