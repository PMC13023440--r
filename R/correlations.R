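## RCB-stratified Spearman correlation networks over the seven IHC markers,
## with per-stratum BH correction and percentile bootstrap confidence
## intervals.

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks handle ties; the p-value is exact for n < 10 without ties
#' (the smallest stratum has n = 7) and the asymptotic t approximation
#' otherwise. A constant input yields an undefined, flagged correlation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `p_raw`, `n`, `flagged`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) abort_nact("nactsig_input_error", "need at least 3 observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, p_raw = NA_real_, n = n, flagged = TRUE))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = n < 10 && !ties)
  )
  list(rho = unname(ct$estimate), p_raw = ct$p.value, n = n, flagged = FALSE)
}

## rho only, for bootstrap loops (ranked Pearson, tie-safe)
spearman_rho_fast <- function(x, y) cor(rank(x), rank(y))

#' Percentile bootstrap confidence interval for a Spearman correlation
#'
#' Resamples (x, y) pairs with replacement `n_resamples` times and returns
#' the 2.5th and 97.5th percentiles of the resampled correlations. A
#' resample in which either coordinate is constant has no defined rank
#' correlation and is redrawn (keeping exactly `n_resamples` valid
#' resamples, so the percentile denominator is fixed); the number of
#' redraws is reported. If the retry budget is exhausted — possible only
#' for tiny, nearly degenerate samples — the record is flagged.
#'
#' @param x,y Paired numeric vectors, length >= 4.
#' @param n_resamples Number of valid resamples (default 1000).
#' @param seed Integer seed or `NULL`.
#' @param max_redraw_factor Retry budget as a multiple of `n_resamples`.
#' @return A list with `ci_low`, `ci_high`, `n_redraws`, `flagged`.
#' @export
bootstrap_ci <- function(x, y, n_resamples = 1000L, seed = NULL,
                         max_redraw_factor = 100) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 4) abort_nact("nactsig_input_error", "need at least 4 observations")
  with_seed_(seed, {
    rhos <- numeric(n_resamples)
    kept <- 0L
    redraws <- 0L
    budget <- max_redraw_factor * n_resamples
    while (kept < n_resamples) {
      idx <- sample.int(n, n, replace = TRUE)
      xi <- x[idx]; yi <- y[idx]
      if (length(unique(xi)) == 1L || length(unique(yi)) == 1L) {
        redraws <- redraws + 1L
        if (redraws > budget) {
          return(list(ci_low = NA_real_, ci_high = NA_real_,
                      n_redraws = redraws, flagged = TRUE))
        }
        next
      }
      kept <- kept + 1L
      rhos[kept] <- spearman_rho_fast(xi, yi)
    }
    q <- unname(quantile(rhos, c(0.025, 0.975)))
    list(ci_low = q[1], ci_high = q[2], n_redraws = redraws, flagged = FALSE)
  })
}

#' RCB-stratified pairwise marker correlations
#'
#' Computes Spearman correlations for all 21 unordered marker pairs within
#' each RCB stratum, applies BH correction separately within each stratum
#' (each stratum's 21 pairs are one family), and attaches percentile
#' bootstrap confidence intervals. Strata with fewer than `min_n` patients
#' emit flagged records with undefined estimates. Significance stars follow
#' the heatmap convention on adjusted p: `*` < 0.05, `**` < 0.01,
#' `***` < 0.001.
#'
#' @param cohort A cohort tibble.
#' @param markers Marker names (default all seven).
#' @param n_resamples Bootstrap resamples per pair (default 1000).
#' @param ci Compute bootstrap intervals? Disable for large simulation
#'   studies that only need rho and p.
#' @param seed Integer seed for the bootstrap, or `NULL`.
#' @param min_n Minimum stratum size to compute (default 4).
#' @return A tibble with `stratum`, `marker1`, `marker2`, `n`, `rho`,
#'   `p_raw`, `p_adj`, `ci_low`, `ci_high`, `n_redraws`, `stars`, `flagged`.
#' @export
stratified_correlations <- function(cohort, markers = nact_markers(),
                                    n_resamples = 1000L, ci = TRUE,
                                    seed = NULL, min_n = 4L) {
  pairs <- combn(markers, 2)
  with_seed_(seed, {
    strata <- lapply(RCB_CLASSES, function(k) {
      sub <- as.data.frame(cohort)[cohort$rcb == k, tolower(markers)]
      n <- nrow(sub)
      rows <- lapply(seq_len(ncol(pairs)), function(j) {
        m1 <- pairs[1, j]; m2 <- pairs[2, j]
        if (n < min_n) {
          return(tibble(stratum = k, marker1 = m1, marker2 = m2, n = n,
                        rho = NA_real_, p_raw = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_redraws = NA_integer_, flagged = TRUE))
        }
        x <- sub[[tolower(m1)]]; y <- sub[[tolower(m2)]]
        sp <- spearman_rho(x, y)
        bs <- if (ci && !sp$flagged) {
          bootstrap_ci(x, y, n_resamples = n_resamples, seed = NULL)
        } else {
          list(ci_low = NA_real_, ci_high = NA_real_,
               n_redraws = NA_integer_, flagged = sp$flagged)
        }
        tibble(stratum = k, marker1 = m1, marker2 = m2, n = n,
               rho = sp$rho, p_raw = sp$p_raw,
               ci_low = bs$ci_low, ci_high = bs$ci_high,
               n_redraws = as.integer(bs$n_redraws %||% NA_integer_),
               flagged = sp$flagged || bs$flagged)
      })
      out <- bind_rows(rows)
      ok <- !is.na(out$p_raw)
      out$p_adj <- NA_real_
      out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
      out
    })
    out <- bind_rows(strata)
    out$stars <- ifelse(is.na(out$p_adj), "",
                 ifelse(out$p_adj < 0.001, "***",
                 ifelse(out$p_adj < 0.01, "**",
                 ifelse(out$p_adj < 0.05, "*", ""))))
    out[c("stratum", "marker1", "marker2", "n", "rho", "p_raw", "p_adj",
          "ci_low", "ci_high", "n_redraws", "stars", "flagged")]
  })
}

#' Count FDR-significant correlation pairs per stratum
#'
#' @param records Output of [stratified_correlations()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Named integer vector of counts (out of 21) per RCB stratum.
#' @export
count_fdr_significant <- function(records, alpha = 0.05) {
  vapply(RCB_CLASSES, function(k) {
    sub <- records[records$stratum == k, ]
    sum(!is.na(sub$p_adj) & sub$p_adj < alpha)
  }, 0L)
}

#' Per-stratum correlation matrix
#'
#' Reshapes the long record table into a symmetric, unit-diagonal matrix of
#' rho values for one stratum.
#'
#' @param records Output of [stratified_correlations()].
#' @param stratum One of `RCB0..RCB3`.
#' @param markers Marker names defining the matrix order.
#' @return A 7 x 7 numeric matrix.
#' @export
correlation_matrix <- function(records, stratum, markers = nact_markers()) {
  m <- matrix(NA_real_, length(markers), length(markers),
              dimnames = list(markers, markers))
  diag(m) <- 1
  sub <- records[records$stratum == stratum, ]
  for (i in seq_len(nrow(sub))) {
    m[sub$marker1[i], sub$marker2[i]] <- sub$rho[i]
    m[sub$marker2[i], sub$marker1[i]] <- sub$rho[i]
  }
  m
}
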