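---
title: "Methods: immune contexture signatures of NACT response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immune contexture signatures of NACT response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nactsig` analyzes tumor immune contexture measured by immunohistochemistry
(IHC) in breast cancer patients treated with neoadjuvant chemotherapy
(NACT). This vignette is the package's account of the underlying science:
the statistical procedures, their assumptions, the tunable parameters, what
the synthetic data generator does and does not emulate, and the design
choices made where the design was genuinely open.

## Data model and outcomes

The atomic input is one patient: age, molecular phenotype (Luminal A,
Luminal B — including Luminal B HER2-positive tumors, which are analyzed
within the Luminal B group — HER2-enriched, TNBC), a Residual Cancer Burden
class (RCB 0–III), and percent-positive cells for seven IHC markers — the
T cell lineage markers CD4 and CD8, the Treg marker FOXP3, and the
checkpoint/exhaustion molecules PD1, CTLA4, LAG3, TIM-3 — each in
[0, 100] percent. One value per marker per patient is assumed; averaging
over multiple tissue images happens upstream. Missing or out-of-range
marker values are validation errors, never imputed: unanalyzable tissue is
excluded before this table exists.

Two response dichotomies are used and must not be conflated:

* `pcr_vs_rd` — pathological complete response (RCB 0) coded 0, residual
  disease (RCB I–III) coded 1. This is the screening/modeling outcome, so
  AUC values describe the probability that an RD patient out-scores a pCR
  patient.
* `sens_vs_res` — chemosensitive (RCB 0–I) vs chemoresistant (RCB II–III).
  This is the outcome for deconvolution-style cell-type comparisons, and
  fixes the sign convention of the rank-biserial effect size (positive =
  higher in chemoresistant).

## Rank statistics

Two-group comparisons use the two-sided Mann–Whitney U test. U is the count
of (resistant, sensitive) pairs with the resistant value larger, with half
credit for ties; the effect size is the rank-biserial correlation
r = 2U/(n₁n₂) − 1. The p-value is exact when the smaller group has at most
8 observations and there are no ties — the smallest RCB stratum has n = 7,
where asymptotic tails are unreliable — and otherwise uses the normal
approximation with tie and continuity corrections. K-group comparisons use
tie-corrected Kruskal–Wallis H with η² = (H − k + 1)/(n − k); under the
null η² can be slightly negative and is reported as computed, because
clipping would bias averages of effect sizes toward the alternative.

Volcano classification of cell-type scores follows the coloring rule used
in such plots: a cell type is sensitive- or resistant-enriched iff its raw
p < 0.05, with the sign of r choosing the side; the conventional ±0.3
effect-size lines are annotations, not part of the rule (the adjusted p is
reported alongside for transparency). Post hoc pairwise tests after an
omnibus comparison are flagged at raw p < 0.05, uncorrected, matching the
starring convention of the figure panels they reproduce.

Multiplicity is handled by Benjamini–Hochberg step-up adjustment within
*declared families*: all 36 cell types form one family; each RCB stratum's
21 correlation pairs form their own family; the univariate screen adjusts
only the top-5 family (below).

## Composite features

From m = 7 markers and the regulatory subset R = {PD1, CTLA4, LAG3, TIM3,
FOXP3}, the feature set is: singles (7), unordered products (21), ordered
ratios (42), and the T cell-contextualized forms (CD8 × R)/CD4 and
(CD4 × R)/CD8 (10) — 80 in total, in a deterministic canonical order with
stable names (`CD8/CD4`, `CD4*CD8`, `(CD8*CTLA4)/CD4`). The contextualized
forms express a regulatory signal relative to the effector/helper balance;
since bulk IHC cannot resolve single-cell co-expression, they are
tissue-level approximations.

Denominators are floored at ε = 0.01 percent — the order of one detectable
positive cell in a typical field — so zero-positivity patients produce
large but finite ratios instead of infinities. The handling of zero
denominators is an open choice (exclusion would be equally defensible); ε
is therefore recorded in the feature matrix's metadata. Useful exact
invariants: ratios are scale-invariant (homogeneity degree 0), products
degree 2, singles and contextualized features degree 1, and reciprocal
ratios multiply to exactly 1 wherever both denominators exceed ε.

## Univariate screen

Each feature is scored by rank-based AUC for `pcr_vs_rd` (ties get half
credit). Features are ranked by AUC *as computed* — no automatic flipping
of features with AUC < 0.5, since the published ranking reports raw AUC and
lets the odds ratio carry the direction; alphabetical order breaks ties
deterministically. The Youden cutoff maximizes J over candidate thresholds
equal to the observed score values under the rule "positive if
score ≥ t", ties broken by the smallest threshold (observed values rather
than midpoints is an arbitrary but deterministic choice). The dichotomized
2×2 (feature-high × RD) is tested by the two-sided Fisher exact test; the
reported odds ratio is the *sample* odds ratio ad/bc — not the conditional
MLE that `fisher.test()` estimates — with the Haldane–Anscombe +0.5 applied
to all cells only when a zero cell occurs, and a Woolf log-normal 95% CI,
whose widths on small cells match the very wide intervals such screens
print. The table orientation (high row, RD column) is reported explicitly
in the output so the direction of each odds ratio is unambiguous. BH
adjustment is applied to the Fisher p-values of the top 5 features by AUC
only, as their own family, mirroring the screening procedure being
reproduced.

## Stratified correlation networks

Within each RCB stratum, Spearman ρ is computed for all 21 marker pairs
(average ranks for ties; exact p for n < 10 without ties, asymptotic t
otherwise), BH-corrected within the stratum, and accompanied by a
percentile bootstrap CI: 1000 paired resamples with replacement, interval =
2.5th–97.5th percentiles. A resample with a constant coordinate has no
defined rank correlation and is redrawn rather than skipped, keeping the
percentile denominator at exactly 1000; the redraw count is reported, and a
record is flagged if the retry budget (100×) is exhausted. Percentile
intervals may exclude the point estimate in pathological resamples, so
`ci_low ≤ ρ ≤ ci_high` is deliberately not an invariant; `ci_low ≤ ci_high
∈ [−1, 1]` is. Strata smaller than 4 yield flagged records. The per-stratum
count of FDR-significant pairs (out of 21) is the coordination summary:
declining counts from RCB 0 to RCB III indicate progressive decoupling of
the immune network. Heatmap stars follow the 0.05/0.01/0.001 convention on
adjusted p.

## Model validation harness

The classifier is a 100-tree probability Random Forest (ranger) with
balanced class weights (w_c = n/(2 n_c)), evaluated by 5-fold stratified
cross-validation: each class is shuffled and dealt round-robin, so every
fold's class counts are within one patient of proportional. Out-of-fold
(OOF) probabilities of RD are recorded once per patient and pooled into a
single pooled OOF AUC; per-fold AUC and average precision (step integral of
the precision–recall curve) are reported alongside, and pooling is
insensitive to fold order by construction. The inference machinery around
the learner is the tested surface:

* **Bootstrap**: 1000 resamples of the (OOF probability, label) pairs;
  single-class resamples are redrawn; mean, median, and the 2.5/97.5
  percentile interval summarize stability.
* **Permutation test**: 1000 label permutations, each re-running the full
  CV pipeline *including a fresh stratified fold draw for the permuted
  labels*; p = (1 + #{null AUC ≥ observed})/(1 + B) (add-one convention,
  floor 1/(B+1)). Re-stratifying per permutation matters: reusing the
  observed partition verbatim makes the permuted labels' per-fold imbalance
  anti-correlate between training and test folds, which biases the null
  mean of the pooled AUC several points below 0.5; with re-stratification
  the null mean sits near 0.5 (slightly above, because each permutation's
  chance feature–label association is shared dataset-wide and so transfers
  weakly from training to test folds).
* **Diagnostics**: confusion counts at OOF probability ≥ 0.5 (RD positive)
  with sensitivity, specificity, PPV, NPV, accuracy as percentages. The
  0.5 threshold is not dictated by the procedure being reproduced, but it
  self-consistently regenerates the printed confusion arithmetic.
* **Importance**: mean decrease in Gini impurity from the model fit on the
  complete dataset, normalized to sum to 1.
* **Baseline comparison**: a clinical-only model (phenotype dummies with
  HER2 as reference — the encoding both models share) trained under the
  *same* fold assignment; Δ pooled OOF AUC plus Δ mean and Δ median of the
  two bootstrap distributions.

The pipeline deliberately reproduces full-dataset feature selection before
cross-validation — the optimism this induces is a documented property of
the procedure being implemented, not an oversight. The interval printed for
a mean fold AUC has no single canonical construction; the package reports
the fold AUCs themselves and the pooled-OOF bootstrap interval, clearly
labeled, and treats neither as a reproduction target.

## The synthetic generator

The generator produces the study conditions, not a tuning dial:

* **Cohort composition**: n = 57 with RCB 0/I/II/III = 20/7/15/15 (so the
  RD prevalence is 37/57 ≈ 0.65); phenotype mixtures per RCB overweight
  HER2 among complete responders and Luminal A in RCB II–III, with
  expected totals near the 13/19/6/19 phenotype split; age ~
  normal(49.6, 8) years truncated at 18.
* **Marker marginals**: log-normal, capped at 100. Locations put medians
  in ≈0.3–1.8 percent; log-scale SDs of 0.9–1.2 give the observed wide
  dynamic range, with PD1/CTLA4 tails beyond 4% positivity. The source
  study prints only medians and ranges, so these are configuration, not
  ground truth.
* **Dependence**: a Gaussian copula per RCB stratum. Rank correlation is
  targeted directly via the exact relation ρ_latent = 2 sin(π ρ_S/6), so
  the generator speaks the same Spearman language as the analysis. Default
  exchangeable targets: 0.7 (RCB 0), 0.8 (RCB I), 0.35 (RCB II), 0.05
  (RCB III) — coordinated responders, decoupled non-responders. Target
  matrices are PSD-repaired by eigenvalue clipping; a repair that moves
  any entry by more than 0.1 is rejected as a configuration error.
* **Planted signal**: CD8 multiplied by 1.6 and CD4 divided by 1.6 in the
  RD classes, so the CD8/CD4 *balance* (shift ×2.56), not any single
  marker, carries the signal — singles shift only ×1.6 and are further
  diluted by their marginal noise. The direction (CD8/CD4 higher in RD)
  follows the published screen's arithmetic: its top feature's AUC above
  0.5 with RD as positive class fixes the direction the raw-AUC ranking
  rewards. The magnitude was chosen once, by simulation, as the smallest
  round factor at which the generator's stated recoverability property
  (CD8/CD4 in the univariate top 5 in at least 80% of seeds at n = 57)
  holds with margin, and is part of the fixed study conditions.
* **Cell-type scores**: 44 samples (22 sensitive / 22 resistant; the split
  is not printed and an even split is the neutral choice) × 36 lineages,
  log-normal with per-group location shifts δ = √2 σ Φ⁻¹((r+1)/2) chosen
  so the population rank-biserial effect equals the configured target;
  defaults plant NK (−0.45), Th1 CD4 (−0.45), non-regulatory CD4 (−0.35)
  toward sensitive and macrophages (+0.35) toward resistant.

All randomness uses R's default Mersenne-Twister stream with a fixed draw
order (per stratum in RCB order: phenotypes, ages, marker block), so a
fixed seed yields byte-identical CSV serializations across platforms.

What the generator does **not** emulate: measurement error of image
analysis, spatial heterogeneity between tissue cores, between-marker
differences in staining sensitivity, phenotype-dependent marker levels
(phenotype affects only the outcome mixture), and any real biological
coupling beyond an exchangeable copula per stratum. Tests that pass on
synthetic cohorts therefore validate the *machinery* — calibration,
invariants, recoverability of planted structure — not clinical claims about
real tumors.

## Problem sizes and tolerances in the test suite

The suite favors exact oracles (brute-force pair enumeration for U and AUC
on all group sizes up to 6, hypergeometric enumeration for Fisher p,
exhaustive threshold scans for Youden) over tolerance checks wherever
feasible. Stochastic calibration checks use sizes chosen to bound Monte
Carlo error well below the assertion band: type-I calibration of the
volcano over 200 seeds × 36 cell types; bootstrap CI coverage of a null
correlation over 500 replicates at n = 100 (binomial SE ≈ 1%, asserted in
[0.92, 0.98] around the nominal 0.95, acknowledging the percentile
method's slight undercoverage); permutation-null centering with 1000
permutations (asserted within ±0.02 of 0.5); and pattern recovery over 100
generator seeds with the ≥80% criteria stated above. Copula fidelity is
checked at n = 200 (±0.1 on ρ) and marginal medians at n = 600 (±20% on
the log scale).

## Known limitations

* The screen's odds-ratio orientation ("feature-high" odds of RD) is
  reported explicitly because published tables do not always state theirs;
  comparisons of OR direction across studies need care.
* Exact Mann–Whitney/Spearman p-values are unavailable under ties; small
  tied strata fall back to approximations whose tails are conservative.
* The percentile bootstrap at n = 7 (RCB I) is honest about instability —
  intervals can span nearly [−1, 1] — but cannot repair it.
* ΔAUC inference is descriptive (point and bootstrap deltas); no formal
  test of the paired AUC difference is attempted, matching the procedure
  reproduced.
* The Random Forest is intentionally fixed (100 trees, balanced weights,
  default mtry): the package validates a published configuration rather
  than searching hyperparameters.
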