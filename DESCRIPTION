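Package: nactsig
Title: Immune Contexture Signatures of Pathological Response to
    Neoadjuvant Chemotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of an immunological-signature
    analysis of pathological response to neoadjuvant chemotherapy in breast
    cancer. From per-patient immunohistochemistry marker positivities (CD4,
    CD8, FOXP3, PD1, CTLA4, LAG3, TIM3) the package engineers 80 composite
    immune features (singles, pairwise products, pairwise ratios, and T
    cell-contextualized forms), screens them univariately by ROC/AUC with
    Youden cutoffs and Fisher exact odds ratios, builds Residual Cancer
    Burden (RCB)-stratified Spearman correlation networks with percentile
    bootstrap confidence intervals, and validates a Random Forest classifier
    with stratified out-of-fold cross-validation, bootstrap and Monte Carlo
    permutation inference, and a clinical-baseline comparison. A synthetic
    cohort generator with Gaussian-copula marker dependence makes every
    stage exercisable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    ranger,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
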