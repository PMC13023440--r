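# nactsig

Immune contexture signatures of pathological response to neoadjuvant
chemotherapy (NACT) in breast cancer.

## The problem

Tumor-infiltrating lymphocytes predict response to NACT, but in many cohorts
the *abundance* of individual immune-cell markers measured by
immunohistochemistry (IHC) — CD4, CD8, FOXP3, and the checkpoint molecules
PD1, CTLA4, LAG3, TIM-3, quantified as percent-positive cells — does not
separate responders from non-responders. What does distinguish them is the
*organization* of the infiltrate: how tightly the markers co-vary, and the
balance between effector and regulatory signals. `nactsig` implements, as a
tested and reusable pipeline, an analysis built on that idea, for
biostatisticians working with IHC marker panels and residual cancer burden
(RCB) outcomes:

1. **Composite feature engineering** — from the seven markers, 80 candidate
   features: singles (7), pairwise products `mi * mj` (21), pairwise ratios
   `mi / mj` (42), and T cell-contextualized forms
   `(CD8 × R)/CD4` and `(CD4 × R)/CD8` for each regulatory marker
   R ∈ {PD1, CTLA4, LAG3, TIM3, FOXP3} (10).
2. **Univariate screening** — per-feature ROC AUC for pathological complete
   response (pCR, RCB 0, class 0) vs residual disease (RD, RCB I–III,
   class 1), Youden-index cutoff J = sens + spec − 1, Fisher exact test on
   the dichotomized 2×2 with sample odds ratio and Woolf 95% CI, and
   Benjamini–Hochberg correction over the top 5 features by AUC.
3. **Stratified correlation networks** — Spearman ρ for all 21 marker pairs
   within each RCB class, BH-corrected per stratum, with 1000-resample
   percentile bootstrap CIs; the count of FDR-significant pairs per stratum
   quantifies immune coordination.
4. **Model validation harness** — a 100-tree Random Forest with balanced
   class weights on the top-5 features plus phenotype dummies, evaluated by
   5-fold stratified cross-validation with pooled out-of-fold (OOF)
   predictions: pooled OOF AUC, 1000-iteration bootstrap of the OOF pairs,
   a one-sided Monte Carlo permutation test
   (p = (1 + #{AUC\* ≥ AUC}) / (1 + B)), Gini importances, diagnostic
   metrics, and ΔAUC against a clinical-only (phenotype dummies) baseline
   under the identical fold assignment.
5. **Group statistics** for deconvolution-style cell-type score matrices —
   Mann–Whitney U with rank-biserial effect size r = 2U/(n₁n₂) − 1
   (positive = higher in chemoresistant), Kruskal–Wallis with
   η² = (H − k + 1)/(n − k), and volcano classification.

Because patient-level data of the motivating study are not public, the
package ships a first-class **synthetic cohort generator**: log-normal
marker marginals coupled by a per-RCB Gaussian copula (coordinated in
responders, decoupled in non-responders), the study's cohort composition
(n = 57; RCB 20/7/15/15), a planted CD8/CD4 balance shift carried by the
composite rather than any single marker, and an xCell-style 44 × 36
cell-type score matrix with planted NK/Th1/non-regulatory-CD4 vs macrophage
enrichment. Every stage is exercisable and testable offline.

## Worked example

```r
library(nactsig)

cohort <- generate_cohort(cohort_config(seed = 42))
summarize_cohort(cohort)
#> Cohort of 57 patients (mean age 50.1)
#> RCB:  RCB0 20 (35.1%), RCB1 7 (12.3%), RCB2 15 (26.3%), RCB3 15 (26.3%)
#> Phenotype:  LuminalA 16 (28.1%), LuminalB 13 (22.8%), HER2 8 (14.0%), TNBC 20 (35.1%)

labels   <- derive_labels(cohort, "pcr_vs_rd")   # 0 = pCR, 1 = RD
features <- compute_features(cohort)             # 57 x 80
screen   <- screen_features(features, labels, top_k = 5)
screen[1:5, c("feature", "auc", "odds_ratio", "ci_low", "ci_high", "p_raw", "p_adj")]
#>           feature   auc odds_ratio ci_low ci_high    p_raw    p_adj
#> 1         CD8/CD4 0.700      31.21   3.75   259.5 1.83e-05 9.17e-05
#> 2  (CD8*TIM3)/CD4 0.668       4.71   1.32    16.8 2.33e-02 2.50e-02
#> 3        TIM3/CD4 0.662       4.71   1.32    16.8 2.33e-02 2.50e-02
#> 4 (CD8*CTLA4)/CD4 0.661       4.40   1.32    14.7 2.50e-02 2.50e-02
#> 5   (CD8*PD1)/CD4 0.645       4.71   1.32    16.8 2.33e-02 2.50e-02
```

The planted CD8/CD4 balance tops the screen (AUC 0.700: a patient with a
high CD8/CD4 ratio has a 70% probability of out-scoring a pCR patient), and
the features sharing its signal fill the remaining top slots. The
multivariate harness then validates the combined signature:

```r
x  <- dplyr::bind_cols(features[screen$feature[1:5]],
                       encode_phenotype_dummies(cohort))
cv <- stratified_cv_oof(x, labels, model_config(seed = 42))
base <- stratified_cv_oof(encode_phenotype_dummies(cohort), labels,
                          model_config(seed = 42),
                          fold_assignment = cv$fold_assignment)
cv$pooled_oof_auc - base$pooled_oof_auc
#> pooled OOF AUC: 0.795 (baseline 0.713, delta +0.082)

perm <- permutation_test(x, labels, model_config(seed = 42),
                         n_permutations = 1000, seed = 43, observed_cv = cv)
#> permutation p = 0.0020 (mean null AUC 0.497)

count_fdr_significant(stratified_correlations(cohort, seed = 44))
#> RCB0 RCB1 RCB2 RCB3
#>   21    3    0    0
```

The correlation-network counts show the planted coordination gradient: the
pCR stratum's marker network is almost fully significant after FDR, the
decoupled RCB III stratum has none — the qualitative signature that
motivates the composite features. `run_pipeline(run_config(seed = 1))` runs
all stages end to end and writes every table, summary, and a
checksummed manifest to an output directory.

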