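test_that("Mann-Whitney U and rank-biserial match hand examples", {
  r1 <- mann_whitney_rb(c(3, 4, 5), c(1, 2))
  expect_equal(r1$U, 6)
  expect_equal(r1$r_rb, 1)

  r2 <- mann_whitney_rb(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$U, 4.5)
  expect_equal(r2$r_rb, 0)

  r3 <- mann_whitney_rb(c(1, 3), c(2, 4))
  expect_equal(r3$U, 1)
  expect_equal(r3$r_rb, -0.5)

  expect_error(mann_whitney_rb(numeric(0), 1:3),
               class = "nactsig_input_error")
})

test_that("U agrees with brute-force pair enumeration on small instances", {
  set.seed(41)
  for (i in 1:200) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    x <- sample(1:8, n1, replace = TRUE)  # replace=TRUE exercises ties
    y <- sample(1:8, n2, replace = TRUE)
    res <- mann_whitney_rb(x, y)
    u <- brute_force_u(x, y)
    expect_equal(res$U, u)
    expect_equal(res$r_rb, 2 * u / (n1 * n2) - 1)
    ## sign convention: swapping group identity flips r exactly
    expect_equal(mann_whitney_rb(y, x)$r_rb, -res$r_rb)
  }
})

test_that("Kruskal-Wallis eta-squared matches the hand-computed example", {
  ## ranks 1..9 give group rank means 2/5/8; H = 12/(N(N+1)) * sum ni(Ri-R)^2
  res <- kruskal_eta2(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(res$H, 7.2)
  expect_equal(res$eta2, (7.2 - 3 + 1) / (9 - 3))
  expect_equal(res$eta2, 0.8667, tolerance = 1e-4)

  expect_error(kruskal_eta2(list(1:3)), class = "nactsig_input_error")
  expect_error(kruskal_eta2(list(1:3, numeric(0))),
               class = "nactsig_input_error")
})

test_that("eta-squared is near zero for evenly shuffled null groups", {
  set.seed(7)
  vals <- sample(seq_len(300))
  res <- kruskal_eta2(split(vals, rep(1:3, each = 100)))
  expect_lt(abs(res$eta2), 0.03)
})

test_that("two-group Kruskal-Wallis agrees with Mann-Whitney", {
  ## For two groups, H equals the squared standardized U, so the chi-square
  ## p matches the two-sided normal-approximation p up to the continuity
  ## correction applied on the Mann-Whitney side.
  set.seed(11)
  x <- rnorm(12)
  y <- rnorm(12, 0.8)
  kw <- kruskal_eta2(list(x, y))
  mw <- mann_whitney_rb(x, y)
  expect_lt(abs(kw$p_raw - mw$p_raw), 0.02)
})

test_that("BH adjustment matches step-up hand computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(0.005, 0.04, 0.05)), c(0.015, 0.05, 0.05))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, 1.2)), class = "nactsig_input_error")
})

test_that("BH adjustment is monotone and never below raw", {
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
  ## step-up fixpoint: a saturated adjusted vector re-adjusts to itself
  expect_equal(bh_adjust(c(0.04, 0.04, 0.04, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
})

test_that("post hoc pairwise comparisons flag separated groups", {
  res <- posthoc_pairwise(list(a = c(1, 2, 3, 4), b = c(9, 10, 11, 12)))
  expect_equal(res$p_raw, 2 / choose(8, 4))  # exact enumeration: 2/70
  expect_true(res$significant)

  same <- posthoc_pairwise(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gte(same$p_raw, 0.99)
  expect_false(same$significant)

  three <- posthoc_pairwise(list(a = 1:3, b = 4:6, c = 7:9))
  expect_identical(nrow(three), 3L)
})

test_that("volcano classification follows the p-and-sign rule", {
  sc <- generate_celltype_scores(celltype_config(seed = 2))
  v <- volcano_table(sc)
  expect_identical(nrow(v), 36L)
  expect_true(all(v$p_adj >= v$p_raw))
  ## classification is a pure function of (r_rb, p_raw)
  expect_identical(
    v$classification,
    ifelse(v$p_raw < 0.05 & v$r_rb < 0, "sensitive-enriched",
           ifelse(v$p_raw < 0.05 & v$r_rb > 0, "resistant-enriched",
                  "non-enriched")))

  ## a constant cell type is tie-saturated: r = 0, p = 1
  sc$Monocytes <- 1
  v2 <- volcano_table(sc)
  expect_equal(v2$r_rb[v2$cell_type == "Monocytes"], 0)
  expect_equal(v2$p_raw[v2$cell_type == "Monocytes"], 1)
  expect_identical(v2$classification[v2$cell_type == "Monocytes"],
                   "non-enriched")

  expect_error(volcano_table(sc, group_labels = rep("sensitive", nrow(sc))),
               class = "nactsig_input_error")
})

test_that("planted NK enrichment is recovered in most seeds", {
  hits <- 0L
  for (s in 1:20) {
    v <- volcano_table(generate_celltype_scores(celltype_config(seed = 300 + s)))
    hits <- hits +
      (v$classification[v$cell_type == "NK cells"] == "sensitive-enriched")
  }
  expect_gte(hits, 12L)
})

test_that("null generator is type-I calibrated at about 5%", {
  null_cfg <- function(s) {
    celltype_config(effect_table = setNames(numeric(0), character(0)),
                    seed = s)
  }
  n_sig <- 0L
  n_tot <- 0L
  for (s in 1:200) {
    v <- volcano_table(generate_celltype_scores(null_cfg(s)))
    n_sig <- n_sig + sum(v$p_raw < 0.05)
    n_tot <- n_tot + nrow(v)
  }
  expect_gt(n_sig / n_tot, 0.03)
  expect_lt(n_sig / n_tot, 0.07)
})
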