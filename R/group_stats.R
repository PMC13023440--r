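## Rank-based two-group and k-group comparisons with effect sizes, BH
## correction, post hoc pairwise tests, and volcano classification of
## cell-type enrichment scores.

## Shared Mann-Whitney policy: exact p when the smaller group has <= 8
## observations and there are no ties (small strata need exact tails),
## normal approximation with tie correction and continuity correction
## otherwise. All-tied data short-circuits to p = 1.
mw_p_value <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Mann-Whitney test with rank-biserial effect size
#'
#' U counts the (resistant, sensitive) pairs where the resistant value is
#' larger, with half credit for ties; the rank-biserial correlation is
#' r = 2U/(n1 n2) - 1, so positive values indicate higher values in the
#' chemoresistant group. Two-sided p-value (exact for small untied groups,
#' tie-corrected normal approximation otherwise).
#'
#' @param values_resistant,values_sensitive Numeric vectors, both nonempty.
#' @param unit_name Optional label carried into the result.
#' @return A one-row tibble with `unit_name`, `U`, `p_raw`, `r_rb`.
#' @export
mann_whitney_rb <- function(values_resistant, values_sensitive,
                            unit_name = NA_character_) {
  if (length(values_resistant) == 0 || length(values_sensitive) == 0) {
    abort_nact("nactsig_input_error", "both groups must be nonempty")
  }
  n1 <- length(values_resistant)
  n2 <- length(values_sensitive)
  r <- rank(c(values_resistant, values_sensitive))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tibble(
    unit_name = unit_name,
    U = U,
    p_raw = mw_p_value(values_resistant, values_sensitive),
    r_rb = 2 * U / (n1 * n2) - 1
  )
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected Kruskal-Wallis H with p from the chi-square reference
#' (k - 1 df) and the effect size eta^2 = (H - k + 1)/(n - k). Under the
#' null eta^2 can be slightly negative; it is reported as computed, not
#' clipped.
#'
#' @param groups List of at least two nonempty numeric vectors.
#' @param unit_name Optional label.
#' @return A one-row tibble with `unit_name`, `H`, `p_raw`, `eta2`, `k`, `n`.
#' @export
kruskal_eta2 <- function(groups, unit_name = NA_character_) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_nact("nactsig_input_error", "need at least two groups")
  }
  if (any(lengths(groups) == 0)) {
    abort_nact("nactsig_input_error", "all groups must be nonempty")
  }
  k <- length(groups)
  n <- sum(lengths(groups))
  if (n <= k) {
    abort_nact("nactsig_input_error", "total n must exceed the number of groups")
  }
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  tibble(unit_name = unit_name, H = H, p_raw = kt$p.value,
         eta2 = (H - k + 1) / (n - k), k = k, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment over one declared family; output
#' order matches input order and values are clipped to \[0, 1\].
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort_nact("nactsig_input_error", "p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Post hoc pairwise Mann-Whitney comparisons
#'
#' One record per unordered pair of groups with the raw two-sided p-value
#' and a significance flag at 0.05, uncorrected — matching the figure-panel
#' convention of starring nominal pairwise differences after an omnibus
#' test.
#'
#' @param groups Named list of at least two nonempty numeric vectors.
#' @param alpha Flag threshold (default 0.05).
#' @return A tibble with `group1`, `group2`, `p_raw`, `significant`.
#' @export
posthoc_pairwise <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    abort_nact("nactsig_input_error", "need at least two groups")
  }
  if (any(lengths(groups) == 0)) {
    abort_nact("nactsig_input_error", "all groups must be nonempty")
  }
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- combn(seq_along(groups), 2)
  out <- apply(pairs, 2, function(ij) {
    p <- mw_p_value(groups[[ij[1]]], groups[[ij[2]]])
    tibble(group1 = nm[ij[1]], group2 = nm[ij[2]], p_raw = p,
           significant = p < alpha)
  })
  bind_rows(out)
}

#' Volcano classification of cell-type enrichment scores
#'
#' Compares every cell type between chemoresistant and chemosensitive
#' samples by two-sided Mann-Whitney with rank-biserial effect size
#' (positive = higher in resistant). Classification follows the volcano
#' coloring rule: `sensitive-enriched` iff p_raw < `alpha` and r_rb < 0,
#' `resistant-enriched` iff p_raw < `alpha` and r_rb > 0, else
#' `non-enriched`; the conventional +/-0.3 effect-size reference lines are
#' annotation only and play no part in classification. BH adjustment is
#' computed over all cell types as one family and reported alongside.
#'
#' @param scores Tibble or data frame of samples x cell types (numeric
#'   columns only are tested), or the output of
#'   [generate_celltype_scores()].
#' @param group_labels Character/factor vector with values `sensitive` and
#'   `resistant`; defaults to the `group` column of `scores` if present.
#' @param alpha Nominal significance threshold (default 0.05).
#' @return A tibble with `cell_type`, `U`, `r_rb`, `p_raw`, `p_adj`,
#'   `classification`.
#' @export
volcano_table <- function(scores, group_labels = NULL, alpha = 0.05) {
  if (is.null(group_labels) && "group" %in% names(scores)) {
    group_labels <- scores$group
  }
  num <- vapply(scores, is.numeric, TRUE)
  mat <- as.data.frame(scores)[num]
  group_labels <- as.character(group_labels)
  if (!all(c("sensitive", "resistant") %in% group_labels)) {
    abort_nact("nactsig_input_error",
               "both sensitive and resistant groups must be present")
  }
  res_idx <- group_labels == "resistant"
  rows <- lapply(names(mat), function(ct) {
    v <- mat[[ct]]
    mann_whitney_rb(v[res_idx], v[!res_idx], unit_name = ct)
  })
  out <- bind_rows(rows)
  names(out)[names(out) == "unit_name"] <- "cell_type"
  out$p_adj <- bh_adjust(out$p_raw)
  out$classification <- ifelse(
    out$p_raw < alpha & out$r_rb < 0, "sensitive-enriched",
    ifelse(out$p_raw < alpha & out$r_rb > 0, "resistant-enriched",
           "non-enriched"))
  out[c("cell_type", "U", "r_rb", "p_raw", "p_adj", "classification")]
}
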