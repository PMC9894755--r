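---
title: "Methods: vaginal metabolome-microbiome analysis of spontaneous preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vaginal metabolome-microbiome analysis of spontaneous preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vagmet)
```

# The scientific problem

Spontaneous preterm birth (sPTB, delivery before 37 completed weeks of
gestation) is a leading cause of neonatal morbidity, and both its risk and
the composition of the vaginal microbiome differ sharply between Black and
White women. The vaginal ecosystem can be measured at mid-gestation on two
coupled layers: 16S rRNA amplicon profiles of the bacterial community
(summarized as relative abundances plus a qPCR estimate of total bacterial
load) and an untargeted LC-MS/MS metabolome of several hundred small
molecules, many of microbial or exogenous (xenobiotic) origin. `vagmet`
implements a complete, reusable analysis chain over these layers:
preprocessing, global structure and clustering, stratified differential
abundance, metabolite-set enrichment, microbe-metabolite correlation
networks on absolute abundances, and a nested cross-validation framework
for predicting sPTB — together with a synthetic cohort generator that makes
every stage testable without access-controlled cohort data.

# Preprocessing model

Raw metabolite measurements are peak areas: strictly positive where the
compound was detected, blank where it fell below the platform's detection
limit. The pipeline treats that missingness as *left-censoring*, which has
three consequences:

* **Per-feature minimum imputation** (`min_impute()`) is the detection-limit
  surrogate used wherever a complete matrix is unavoidable — distance
  computation for clustering and the prediction feature pipeline. Rank-based
  association tests and all correlation analyses run on observed values
  only and never impute.
* **Detection summaries** (`detection_summary()`) depend only on the
  missingness mask; "detected in over half the cohort" is a strict
  `> 0.5`, and counts are reported over all features and over the named
  subset, since either denominator is defensible for an untargeted panel.
* The generator reproduces the mechanism: a feature's values below its
  detection-threshold quantile are masked, so detection fractions fall
  monotonically as the censoring quantile rises.

Measurements are volume-normalized to the extraction buffer volume, log10
transformed, and **robustly standardized**: per feature, subtract the
median of observed values and divide by the standard deviation of the
values that remain after *excluding* the top and bottom `ceiling(0.05 * n)`
order statistics (an n-1 denominator on the retained values). We read
"clipping the top and bottom 5%" as trimming rather than winsorizing: the
trimmed estimator fully removes the leverage of single extreme peaks, which
is the stated purpose of the robustification. The choice matters little for
well-behaved features and is localized in `trimmed_sd()` should a
winsorized variant ever be preferred. Standardization statistics use
observed values only; features with zero trimmed dispersion are excluded
with an explicit reason rather than silently zeroed.

# Distances, clustering and the number of metabolite clusters

Metabolome sample-sample distances use the **Canberra** metric with the
`|x - y| / (|x| + |y|)` coordinate convention and `0/0` terms contributing
zero. This convention (the one used by common Python scientific stacks)
differs from base R's `dist(method = "canberra")`, which divides by
`|x + y|`; on standardized (signed) data the two disagree, so the package
ships its own small C++ kernel and cross-checks it against a plain-R oracle
in the tests. Canberra weights all features comparably and is insensitive
to single outlying coordinates, which suits heavy-tailed metabolome data.
Microbiome distances are Bray-Curtis on non-negative abundances via
`vegan`.

Clustering is **k-medoids**. We use PAM's deterministic BUILD
initialization followed by SWAP (via `cluster::pam`), rather than random
restarts: given the distance matrix and `k` the solution is bit-for-bit
reproducible, which removes restart variance from the robustness procedure
below. The number of clusters is chosen with the **gap statistic**
(`select_k_gap()`): for each `k` in 1..15, `Gap(k)` compares the log of the
total within-cluster distance-to-medoid against its mean under `B`
reference datasets drawn uniformly over each feature's observed range. The
headline `chosen_k` is the standard one-SE rule (the smallest `k` whose gap
is within one reference-SE of the next gap); the argmax of the curve is
reported alongside, since with a uniform-box reference the raw gap tends to
increase with `k` on real-shaped data and the one-SE rule is the criterion
that actually stops. `B = 50` is the default; desk-scale analyses in the
tests use `B = 20`, which we found equally stable on cohorts of this size.

**Cluster robustness** (`cluster_robustness()`) re-clusters 100 random
90% subsamples de novo at the reference `k` and scores each refit against
the reference assignment (restricted to the subsample) by
maximum-overlap one-to-one label matching — an optimal assignment problem
solved exactly with a small Hungarian-method implementation (no installed
package provides one; it is brute-force verified in the tests). Reported
are the per-subsample matched fractions, their mean, and the count above
95%. Subsampling at fixed `k` is the conservative reading of "recreating
clusters de novo with the same procedure"; re-selecting `k` per subsample
would conflate model-selection variance with assignment stability.

**PERMANOVA** is implemented directly from the among/within decomposition
of squared distances with label permutation, a `+1` numerator/denominator
floor (a permutation p-value is never exactly zero), and an
exhaustive-enumeration mode used by the test oracles; `vegan::adonis2` is
the independent cross-check, never the implementation. The Mantel test
(Spearman over upper triangles, joint row/column permutation) follows the
same pattern.

# Stratified association scans

Per-metabolite differential abundance between outcome groups uses
two-sided Mann-Whitney U tests on observed values (tie-corrected normal
approximation with continuity correction; exact enumeration when
`n_case * n_ctrl <= 400` and the feature is tie-free). Features detected in
under half of the *analyzed stratum* are excluded before testing — each
stratified scan stands alone, so prevalence is judged within the stratum —
and Benjamini-Hochberg q-values are computed across the features actually
tested in that stratum. The default strata are the full cohort, Black and
White women, the progesterone-free subsets of each, and early-delivery
contrasts (before 32 and before 28 weeks) restricted to Black women, where
early deliveries concentrate. For the early contrasts the comparison group
is configurable between "all other births in the stratum" (default) and
term births only; the package asserts neither as canonical. Multi-stratum
summaries order features by the mean over strata of
`direction * (-log10 p)`.

The scan is internally vectorized (rank matrices against label-indicator
matrices), which is what makes the enrichment permutation null below
affordable; `stats::wilcox.test` is the per-feature oracle in the tests.

# Metabolite-set enrichment by permutation

For each functional set (Metabolon super-pathways, sub-pathways, and KEGG
pathways with at least two annotated members), the observed statistic is a
*second-level*, one-sided Mann-Whitney p-value asking whether the per-feature
association p-values inside the set are stochastically smaller than those
outside it. Because that statistic's null distribution under feature
correlation is not analytic, it is calibrated empirically: outcome labels
are permuted within the stratum, the *entire* per-feature scan and the
second-level statistic are recomputed through the identical code path, and
`perm_p = (1 + #{null <= observed}) / (1 + B)` with `B = 10000` by default
(1000 in desk-scale runs). Three design points matter:

* the prevalence filter is applied once to the observed stratum and the
  feature universe is frozen across permutations — label shuffles cannot
  change detection masks, and letting the universe drift would break
  exchangeability;
* all sets share the same permutation stream, so across-set comparisons and
  the within-set-type BH correction are coherent;
* per-feature null p-values are computed once per permutation and reused by
  every set, making the scan linear rather than quadratic in practice.

Sidedness of the second-level test is one-sided by default ("enriched for
associations" is directional); a two-sided flag exists. FDR correction is
applied separately within each set type, never across types.

# Microbe-metabolite networks on absolute abundances

Relative abundances confound correlation analysis; multiplying each
sample's composition by its total 16S copy number gives absolute-scale
abundances (`estimate_absolute_abundance()`). Samples without a qPCR load
are excluded here — not imputed — and recorded. Spearman correlations are
computed between taxa and (typically sPTB-associated) metabolites on
pairwise-complete observations: a missing metabolite value drops the pair,
while a taxon zero is an observed absence and is kept. Edges require a
minimum number of complete pairs; the fraction-based contract is
`ceiling(0.22 * n_cohort)` (52 of 232); an explicit integer threshold
(50 is the commonly quoted figure for a 232-sample cohort) is settable
directly. The two conventions differ by two samples and the package
surfaces both rather than resolving the discrepancy. Kept edges additionally satisfy `BH q < 0.1` and
`|rho| > 0.25`.

Race- and severity-dependence of individual edges is tested with the
Fisher r-to-z transform, `z = (atanh(r_a) - atanh(r_b)) / sqrt(1/(n_a-3) +
1/(n_b-3))`; the classical `1/(n-3)` variance is the default (the cited
transform's standard usage) with the `1.06/(n-3)` rank-correlation variant
behind a flag. Whole-group edge-strength contrasts (e.g. xenobiotic-like
metabolites versus the rest) compare `|rho|` distributions with a
two-sided Mann-Whitney test.

# Predicting sPTB: race-composite nested cross-validation

The prediction framework estimates generalization honestly on a small,
heterogeneous cohort:

* **Outer loop**: 10-fold cross-validation, block-stratified on deciles of
  gestational age at birth (computed on the full cohort, used for
  stratification only, never as a feature) and — for metabolome,
  microbiome and combined models — on the binary race grouping
  `{Black, non-Black}`; repeated 5 times from seed substreams.
* **Inner loop**: each outer training set is split 5-fold, 5 times; every
  hyperparameter candidate is evaluated on all 25 inner cells.
* **Selection rule**: candidates are ranked by mean inner R² — read as the
  coefficient of determination of the predicted probability against the
  0/1 outcome, the natural probability-scale reading of "R² for
  classification" (a squared-Pearson alternative exists behind the same
  interface) — and among the top five the best mean inner auROC wins, ties
  broken by draw order.
* **Composite models** fit one pipeline + learner per race stratum on that
  stratum's training rows only; a sample is always scored by its own
  stratum's model, and pooled out-of-fold scores are exactly the
  concatenation of per-stratum scores.
* **Sterility is structural**: every statistic a pipeline step needs
  (standardization centers and trimmed SDs, imputation minima, PCA
  rotations, selection scores, the mean qPCR load used to fill missing
  loads in microbiome features) is computed from training rows and stored
  in the fitted pipe; scoring reuses the stored values.

The feature pipeline is standardize → impute → (either) PCA (or) feature
selection, followed by a gradient-boosted tree ensemble (xgboost;
missing values flow to the trees' native default-direction handling when
imputation is off). Candidates draw either a PCA transform or a selection
step — selection scores on principal components mix poorly with the
sparsity and importance criteria, so the space treats the two transforms
as alternatives. Selection scores (absolute Spearman correlation
with the outcome, information gain of the median split, detection
fraction, or probe-model tree importance) are computed once per training
fold on a fixed standardized-and-imputed basis and cached; they are
deterministic functions of training data only. The learner sits behind a
narrow fit/predict contract, so the framework's contracts are tested with
a deterministic linear stub as well.

The default search space is deliberately desk-scale: shallow trees (depth
2-3), 6-24 boosting rounds, learning rate 0.08-0.6, subsampling and column
sampling, L2 regularization, selection strengths of 10-80 features, PCA
ranks of 5-20. Larger budgets (say, 1000 candidates) are reachable by
passing a larger candidate table; the package default benchmark uses 50.
Reported problem sizes for the shipped simulations: 232 samples, 200
metabolite features, 50 candidates, 10x5 outer and 5x5 inner folds for the
acceptance suite; 20 candidates and 10x2/5x2 folds in the acceptance
script.

Evaluation pools out-of-fold scores per repeat; auROC is the midrank
statistic (ties count half), auPR is step-integrated precision over
recall. Reclassified outcomes (delivery before 32 or 28 weeks) change only
the ground-truth labels — the score vectors are reused byte-identically.
auROC differences between models use Hanley-McNeil standard errors. The
final model refits each outer-cell-selected candidate on the whole cohort
and picks the best *training-fit* auROC; that metric is explicitly flagged
as a training fit, not a generalization estimate. External application
maps features by identifier, standardizes with training statistics, fills
unmeasured features with the training post-standardization median (exactly
0 under median centering — the neutral value under the standardization
contract), and never retrains; TreeSHAP attributions come from the tree
ensemble's native additive-contribution computation.

# The synthetic cohort generator

`generate_cohort()` draws cohorts with the statistical structure the
analyses assume; its defaults encode the cohort structure the package
targets: 232 samples with
80 sPTB cases, 71% Black women, six metabolome sample clusters, and a
left-censored untargeted panel. Where the underlying reports give no
value, defaults were chosen once as field-realistic and are stated here:

* 40 taxa with five CST-like composition profiles (four dominated by a
  single *Lactobacillus*-like taxon via high-concentration Dirichlet
  weight, one diverse anaerobe-rich profile), CST probabilities
  (0.35, 0.07, 0.28, 0.25, 0.05); total loads log-normal with
  `meanlog = log(1e7)`, `sdlog = 1`; 6% of samples lack a load value.
* 150 named + 30 unnamed features at desk scale (635 + 110 at study
  scale in the acceptance script); feature log10 means `N(5, 1)`, SDs
  uniform on (0.3, 0.8); cluster blocks shift 40% of features by ±3
  feature-SDs.
* 60% of features are censored at a uniform quantile below 0.45, keeping
  expected detection above the 50% prevalence filter.
* Gestational age at birth: term uniform on 38-41 weeks; sPTB triangular
  on (21, 36.9) peaked at 35, giving a realistic early-delivery tail for
  the <32/<28-week strata.
* Outcome assignment tilts case sampling by a PTB-history odds ratio of 3
  (the planted "weak clinical covariate"); metabolome effects are then
  planted as case shifts in SD units, equivalent to outcome dependence on
  those features and exactly reproducible from the truth record.
* Planted features (case shifts, enriched-set members, coupled features)
  are kept out of the cluster blocks so a planted "0.8 SD shift" or
  "strength 0.7 coupling" is realized on the feature's actual SD scale
  rather than diluted by block variance; couplings mix a standardized
  log-absolute-abundance signal into the feature's noise so the latent
  correlation equals the stated strength; xenobiotic-like features are
  generated taxa-independent by construction.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: peak-shape and retention-time artifacts,
batch effects beyond additive offsets, compositional sequencing noise and
read-depth variation, phylogenetic correlation among taxa, nonlinear
microbe-metabolite dose-response, and the correlated block structure of
real biochemical pathways beyond the planted sets. Passing the suite shows
the machinery is correct and calibrated under the stated generative model,
not that any biological conclusion transfers.

# Numerical choices and degenerate inputs

Permutation p-values always carry the `+1` floor. Canberra `0/0` terms
contribute zero. Constant features are excluded with reasons at
standardization and inside scans; constant vectors in the network are
recorded as uncomputed pairs. The Mann-Whitney normal approximation uses
midrank tie correction and a continuity correction of 0.5, switching to
exact enumeration only in the tie-free small-sample regime (both branches
agree to |Δp| < 0.01 where they overlap). k-medoids at `k = n` returns the
trivial zero-dispersion solution without invoking PAM. All randomness
flows from one master seed through named substreams
(`substream_seed(master, name, index)`), so adding a stage or resizing one
loop never perturbs another stage's draws, and identical (config, seed)
runs are byte-identical.

# Known limitations

* The deposited cohort's raw table is access-controlled; the three
  cohort-level acceptance checks (detection counts 549/108, feature counts
  635/110, the ~86% robustness figure) run only when a user supplies that
  table at `inst/extdata/deposited_raw_metabolites.tsv`.
* Constraint-based community metabolic modelling (AGORA-style models,
  NMPC computation), which often complements correlation networks in this
  field, is out of scope here, as is upstream 16S read processing
  and LC-MS/MS peak identification: tables in, tables out.
* The composite predictor's race grouping is binary; "Other" joins
  non-Black, which follows the external-validation usage but is a coarse
  choice.
* The gap statistic's uniform-box reference is simple and fast; a
  PCA-aligned reference would be more conservative for elongated data
  clouds.
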