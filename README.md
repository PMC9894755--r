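# vagmet

Integrated analysis of the vaginal metabolome and microbiome in pregnancy
cohorts with spontaneous preterm birth (sPTB) outcomes.

Mid-gestation vaginal samples can be profiled on two coupled layers: 16S
rRNA community composition (relative abundances plus a qPCR estimate of
total bacterial load) and an untargeted LC-MS/MS metabolome with
left-censored, detection-limit missingness. `vagmet` is an R package for
epidemiologists and microbiome researchers who need to take such paired
tables from raw measurements to calibrated statistics and honest
predictive benchmarks:

- **Preprocessing** — volume normalization, log10 transform, robust
  standardization ((x − median) / SD after trimming the top and bottom 5%
  order statistics), detection summaries, per-feature-minimum
  (detection-limit) imputation.
- **Global structure** — Canberra (|x−y|/(|x|+|y|)) and Bray–Curtis
  distances, PERMANOVA and Mantel tests with permutation nulls and the
  +1 floor, k-medoids (PAM) clustering with gap-statistic selection of k
  (one-SE rule) and a 100×90% subsample robustness score based on optimal
  (Hungarian) cluster matching.
- **Associations** — stratified two-sided Mann–Whitney scans (whole
  cohort, race strata, progesterone-free subsets, early-delivery
  contrasts) with within-stratum prevalence filtering and
  Benjamini–Hochberg control.
- **Set enrichment** — a permutation-null test for whether a metabolite
  set (super-/sub-pathway, KEGG) is enriched for outcome associations:
  the in-set versus out-of-set second-level Mann–Whitney p-value is
  calibrated against the same statistic under thousands of outcome-label
  permutations, `perm_p = (1 + #{null ≤ observed}) / (1 + B)`.
- **Microbe–metabolite networks** — Spearman correlations between
  qPCR-scaled absolute abundances and metabolite levels on
  pairwise-complete data (never imputed), with pairing thresholds, FDR
  and |ρ| edge filters, Fisher r-to-z subgroup comparisons, and
  edge-strength contrasts between feature groups.
- **Prediction** — a race-composite, block-stratified nested
  cross-validation framework (10×5 outer, 5×5 inner folds) around a
  gradient-boosted tree learner with an in-pipeline
  standardize/impute/PCA/feature-selection search, an R²-then-auROC
  selection rule, reclassified-outcome evaluation, Hanley–McNeil auROC
  comparison, final-model selection, external-cohort application and
  TreeSHAP attributions.
- **Synthetic cohorts** — a generator with planted, recorded ground truth
  (cluster blocks, case shifts, microbe–metabolite couplings,
  xenobiotic-like taxa-independent features, enriched sets, left
  censoring) that makes every stage testable end to end.

## Worked example

```r
library(vagmet)

cfg <- sim_config(
  n_samples = 232, n_cases = 80,
  effects   = sim_effects(10, shift = 0.8),                  # planted sPTB shifts
  couplings = sim_couplings(10, strength = 0.7, feature_from = 21),
  seed = 1
)
cohort <- generate_cohort(cfg)

std <- preprocess_pipeline(cohort$matrix)         # log10 + robust standardize + impute
gap <- select_k_gap(std, k_range = 1:15, B = 20, seed = 1)
gap
#> <gap_curve> k in [1, 15], chosen k = 6 (one-SE), argmax k = 15

rob <- cluster_robustness(compute_distance(std), gap$fit,
                          n_subsamples = 100, fraction = 0.9, seed = 1)
rob
#> <robustness_report> 100 subsamples of 90%: mean accuracy 100.0%, 100 above 95%

assoc <- association_scan(cohort$matrix, cohort$metadata, strata = "all")
sum(assoc$q < 0.1)                                 # planted features surface
#> [1] 10
```

The chosen `k = 6` matches the six planted metabolome sample clusters; the
robustness report says every 90% subsample reproduced the full-cohort
cluster assignment (on real, noisier cohorts this averages well below 1).
The association scan recovers exactly the 10 planted case-shifted
features at `q < 0.1`, with no false discoveries among the other 170.

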