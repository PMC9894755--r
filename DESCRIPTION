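Package: vagmet
Title: Integrated Vaginal Metabolome-Microbiome Analysis for Spontaneous
    Preterm Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for joint analysis of vaginal
    metabolome and microbiome profiles in pregnancy cohorts with spontaneous
    preterm birth (sPTB) outcomes. Covers untargeted-metabolomics
    preprocessing (volume normalization, log transform, robust
    standardization, detection summaries, detection-limit imputation),
    global-structure analysis (Canberra and Bray-Curtis distances, PERMANOVA,
    Mantel tests, k-medoids clustering with gap-statistic model selection and
    subsample robustness scoring), stratified Mann-Whitney association scans
    with Benjamini-Hochberg control, a permutation-null metabolite-set
    enrichment test, microbe-metabolite Spearman correlation networks on
    qPCR-scaled absolute abundances with Fisher r-to-z subgroup contrasts,
    and a race-composite nested cross-validation framework for sPTB
    prediction with gradient-boosted trees. A synthetic cohort generator
    with planted, recorded ground truth makes every stage testable end to
    end without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    xgboost
LinkingTo: Rcpp
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
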