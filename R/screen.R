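## Per-feature discrimination analysis: ROC/AUC, Youden cutoff, dichotomized
## Fisher exact test with odds ratio and Woolf confidence interval, and
## top-k ranking with an FDR family restricted to the top features.

#' Rank-based ROC AUC
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(tie), with label 1 (residual
#' disease) as the positive class, computed from ranks (equivalent to the
#' Mann-Whitney statistic scaled by n1 n0). Features are screened as-is:
#' values below 0.5 are reported unflipped.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector of the same length, both classes present.
#' @return The AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    abort_nact("nactsig_input_error", "both classes must be present")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal dichotomizing threshold
#'
#' Scans candidate thresholds (the observed unique score values) under the
#' rule "positive if score >= t" and returns the threshold maximizing
#' Youden's J = sensitivity + specificity - 1, ties broken by the smallest
#' threshold.
#'
#' @inheritParams roc_auc
#' @return A list with `threshold` and `youden_j`.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    abort_nact("nactsig_input_error", "both classes must be present")
  }
  thresholds <- sort(unique(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  j <- vapply(thresholds, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, 0)
  best <- which.max(j)  # which.max takes the first (= smallest) maximizer
  list(threshold = thresholds[best], youden_j = j[best])
}

#' Dichotomize at a threshold and test the 2x2 association
#'
#' Builds the 2x2 table of feature-high (score >= threshold) versus the
#' binary outcome (label 1 = residual disease). Reports the sample odds
#' ratio ad/(bc), applying the Haldane-Anscombe +0.5 correction to all four
#' cells only when some cell is zero, with a Woolf log-normal 95% confidence
#' interval, and the two-sided Fisher exact p-value computed on the
#' uncorrected counts. A degenerate margin (all patients high or all low)
#' yields a flagged record with p = 1 and undefined odds ratio.
#'
#' @inheritParams roc_auc
#' @param threshold Dichotomizing threshold.
#' @return A list with `table` (2x2 matrix, rows high/low, columns RD/pCR),
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_raw`, `degenerate`.
#' @export
dichotomize_and_test <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0)) {
    abort_nact("nactsig_input_error", "both classes must be present")
  }
  high <- scores >= threshold
  tab <- matrix(c(sum(high & labels == 1), sum(high & labels == 0),
                  sum(!high & labels == 1), sum(!high & labels == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("high", "low"), c("RD", "pCR")))
  if (all(high) || all(!high)) {
    return(list(table = tab, odds_ratio = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_raw = 1, degenerate = TRUE))
  }
  cells <- as.numeric(t(tab))  # a=high-RD, b=high-pCR, c=low-RD, d=low-pCR
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  list(
    table = tab,
    odds_ratio = or,
    ci_low = exp(log(or) - qnorm(0.975) * se),
    ci_high = exp(log(or) + qnorm(0.975) * se),
    p_raw = fisher.test(tab)$p.value,
    degenerate = FALSE
  )
}

#' Univariate feature screen
#'
#' Scores every feature against the binary outcome: AUC, Youden cutoff and
#' J, dichotomized 2x2 Fisher test with sample odds ratio and Woolf CI.
#' Features are ranked by AUC descending (ties broken alphabetically by
#' name), and BH adjustment is applied to the Fisher p-values of the top
#' `top_k` features only, as their own family; other features carry
#' `p_adj = NA`.
#'
#' @param feature_matrix Output of [compute_features()] (`patient_id`
#'   column ignored for scoring).
#' @param labels 0/1 outcome aligned to rows (1 = residual disease).
#' @param top_k Size of the reported/adjusted top family (default 5).
#' @return A tibble sorted by rank with columns `feature`, `auc`, `cutoff`,
#'   `youden_j`, `n_high_rd`, `n_high_pcr`, `n_low_rd`, `n_low_pcr`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_raw`, `p_adj`, `rank`.
#' @export
screen_features <- function(feature_matrix, labels, top_k = 5L) {
  feats <- as.data.frame(feature_matrix)
  feats$patient_id <- NULL
  if (top_k > ncol(feats)) {
    abort_nact("nactsig_config_error",
               sprintf("top_k (%d) exceeds feature count (%d)",
                       top_k, ncol(feats)))
  }
  rows <- lapply(names(feats), function(fn) {
    sc <- feats[[fn]]
    yc <- youden_cutoff(sc, labels)
    dt <- dichotomize_and_test(sc, labels, yc$threshold)
    tibble(
      feature = fn,
      auc = roc_auc(sc, labels),
      cutoff = yc$threshold,
      youden_j = yc$youden_j,
      n_high_rd = dt$table["high", "RD"], n_high_pcr = dt$table["high", "pCR"],
      n_low_rd = dt$table["low", "RD"], n_low_pcr = dt$table["low", "pCR"],
      odds_ratio = dt$odds_ratio, ci_low = dt$ci_low, ci_high = dt$ci_high,
      p_raw = dt$p_raw
    )
  })
  out <- bind_rows(rows)
  out <- out[order(-out$auc, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out$p_adj <- NA_real_
  out$p_adj[seq_len(top_k)] <- bh_adjust(out$p_raw[seq_len(top_k)])
  out
}

#' Write a ranked screening table to CSV
#'
#' @param screen Output of [screen_features()].
#' @param path Output path.
#' @param top_k Number of rows to write (default all).
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(screen, path, top_k = nrow(screen)) {
  write.csv(as.data.frame(head(screen, top_k)), path, row.names = FALSE)
  invisible(path)
}
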