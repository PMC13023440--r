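## Shared fixtures: tiny cohorts built in code.

tiny_cohort_df <- function(rcb = c("0", "I", "II", "III"),
                           phenotype = rep("TNBC", length(rcb)),
                           markers = NULL) {
  n <- length(rcb)
  df <- data.frame(
    patient_id = sprintf("T%02d", seq_len(n)),
    age = seq(40, by = 1, length.out = n),
    phenotype = phenotype,
    rcb = rcb,
    stringsAsFactors = FALSE
  )
  if (is.null(markers)) {
    set.seed(99)
    for (m in tolower(nact_markers())) df[[m]] <- round(runif(n, 0.1, 4), 3)
  } else {
    for (m in names(markers)) df[[m]] <- markers[[m]]
  }
  df
}

tiny_cohort <- function(...) as_cohort(tiny_cohort_df(...))

## Cohort whose seven markers are all set from a named list of length-n
## vectors (marker names uppercase).
cohort_with_markers <- function(values, rcb = NULL) {
  n <- length(values[[1]])
  if (is.null(rcb)) rcb <- rep("0", n)
  df <- tiny_cohort_df(rcb = rcb)
  for (m in names(values)) df[[tolower(m)]] <- values[[m]]
  as_cohort(df)
}

## Brute-force oracles -----------------------------------------------------

## Mann-Whitney U by direct pair enumeration (half credit for ties).
brute_force_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
  u
}

## AUC by direct pair counting over (positive, negative) pairs.
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  brute_force_u(pos, neg) / (length(pos) * length(neg))
}

## Two-sided Fisher exact p by enumeration of all tables with fixed margins
## (hypergeometric likelihood rule, with R's relative tolerance).
brute_force_fisher_p <- function(tab) {
  m <- sum(tab[, 1])  # RD total
  nn <- sum(tab[, 2]) # pCR total
  k <- sum(tab[1, ])  # high total
  a_all <- max(0, k - nn):min(k, m)
  probs <- dhyper(a_all, m, nn, k)
  p_obs <- dhyper(tab[1, 1], m, nn, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exhaustive-scan Youden oracle.
brute_force_youden <- function(scores, labels) {
  ths <- sort(unique(scores))
  best_j <- -Inf
  best_t <- NA
  for (t in ths) {
    pred <- scores >= t
    j <- mean(pred[labels == 1]) + mean(!pred[labels == 0]) - 1
    if (j > best_j + 1e-12) {
      best_j <- j
      best_t <- t
    }
  }
  list(threshold = best_t, youden_j = best_j)
}
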