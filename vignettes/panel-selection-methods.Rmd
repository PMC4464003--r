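---
title: "Methods: GA-driven panel selection with IDI-gated stepwise refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GA-driven panel selection with IDI-gated stepwise refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Case-control biomarker studies in dementia research produce wide tables:
a few hundred candidate measurements per subject drawn from structural
MRI (regional volumes, cortical thicknesses, surface areas), FDG-PET
metabolic rates, CSF and plasma assays, and binary clinical-history
flags — with substantial, feature-specific missingness. The goal is a
compact logistic-regression panel (typically 3–8 features) that separates
two diagnostic classes (healthy controls, mild cognitive impairment, or
Alzheimer's disease, compared pairwise), together with an honest estimate
of how well that panel will classify unseen subjects and of how likely an
equally good panel would be found by chance.

`paneldx` implements that workflow end to end. This vignette records the
model, the tunable parameters, the numerical choices, and the places
where the design was genuinely open, so the package's behaviour can be
audited without reading the code.

## Preprocessing

Every feature is z-standardized over **all subjects in the loaded
table** — all classes pooled — and the per-feature (μ~j~, σ~j~) pairs are
recorded on the returned table. Standardizing on the full population
(rather than per contrast) keeps a feature's scale identical across the
three pairwise analyses and makes coefficients comparable between
models. σ~j~ is the sample standard deviation (n − 1 denominator). Binary
flags are variables like any other and are standardized identically; a
constant column is a hard error, since z is undefined at σ = 0.

Missingness is handled by two rules and nothing else:

* **Per-contrast feature filter.** After restricting to the two classes
  of an analysis, a feature missing for *strictly more than* 20% of the
  subjects of either class is excluded (ties at exactly 20% are kept).
* **Complete-case model fits.** Every model evaluation — GA fitness, IDI
  comparison, final fit, validation — uses exactly the subjects with
  complete data on that model's features.

There is no imputation. The order (standardize on the full table, then
filter per contrast) is a deliberate choice: the alternative order would
make μ~j~, σ~j~ depend on which contrast is being run.

## The genetic-algorithm search

The wrapper search evolves fixed-size feature subsets ("chromosomes",
default size 5) scored by stratified k-fold cross-validated accuracy of
the subset's logistic regression (k = 3 or 4 depending on the contrast's
sample size; accuracy thresholds predicted probability at 0.5). The
search is repeated `n_ga_models` = 1,000 times (run r is seeded
`rng_seed + r`), and each run's final best chromosome contributes its
five features to a frequency table.

GA internals are standard wrapper-GA practice and exposed in
`analysis_spec()`: population 50, tournament selection of size 2,
uniform crossover with repair to distinct genes, per-gene mutation
probability 0.02 (a mutated slot is replaced by a uniformly random unused
feature), elitism preserving the single best chromosome, and a fixed 300
generations with no early stopping. Fitness is evaluated in compiled code
with a short Newton iteration (5 steps): the classification boundary —
all that accuracy sees — stabilises within a few steps, and capping the
iteration bounds runaway coefficients under fold-level separation. A
fold whose training rows hold one class is skipped; a chromosome with no
scorable fold gets fitness 0. Within a run, fitness values are cached by
gene set (a chromosome is a set, so the sorted gene tuple is canonical).

## Frequency merging and ranking

Highly correlated features (left/right homologues, volume vs thickness of
the same structure) split frequency between themselves. The ranking
therefore walks features in descending raw frequency (ties broken by
higher mean fitness of the models containing the feature, then by name)
and lets each retained feature absorb every not-yet-absorbed
lower-frequency feature with Pearson |ρ| > 0.8 at p < 0.05 (two-sided
t-test on the pair's complete observations; pairs with fewer than three
complete observations are skipped with a warning). The absorbed feature
leaves the ranking and transfers its raw frequency, so the total is
conserved. A deterministic greedy pass in frequency order is used because
"for every pair" does not itself define an order; transferring toward the
more frequent feature fixes the direction.

## Forward selection and backward elimination

Both stages are gated by the **integrated discrimination improvement**
between nested models, computed on *cross-validated* out-of-fold
probabilities rather than resubstitution fits: each subject is scored by
the model fit on the other k − 1 folds, with one subject-keyed stratified
fold assignment drawn per stage (seeded from `rng_seed` plus a stage tag)
and shared by every comparison in that stage. Pencina's estimator is used
as the normative definition: IDI is the difference in mean predicted
probability gains between events and non-events; its standard error
combines the within-group sample SDs of the per-subject gains; p-values
are two-sided. The forward gate additionally requires IDI > 0.

* **Forward selection** walks the merged ranking (top 50 by default)
  starting from the intercept-only model, adding a candidate only when
  the gate passes on the complete cases of the extended feature set.
  Failing candidates are *skipped* and the walk continues — final panels
  mixing high and low ranks are expected — though a stop-at-first-failure
  variant is available (`fs_stop_at_failure`).
* **Backward elimination** repeatedly computes, for each feature f in the
  current model, the IDI of the full model over the model without f, and
  removes the feature with the smallest z-score provided its p exceeds
  0.05, refitting after each removal until every remaining feature is
  significant.

The classical maximum-fitness rule over nested models is *not* applied;
the IDI gate alone is the operative inclusion criterion.

Calibration of the IDI z-test was checked by simulation: with k = 3 and
n = 100 per class, adding a pure-noise feature to a one-signal parent
rejects at rates slightly above nominal (≈ 0.07–0.08 at α = 0.05 across
independent 1,000-simulation batches) — a known mild anti-conservatism of
the variance estimator under cross-validated probabilities that grows
with k (≈ 0.13 at k = 5, ≈ 0.23 at k = 10 in the same setup). The
pipeline's small k keeps the gate close to its nominal size; the backward
pass re-tests every inclusion, which removes most false entries.

## Validation

The final panel's features act as a new filter: subjects originally
excluded from feature selection but complete on the panel's features form
the **a-posteriori included subjects (APIS)** set. A seeded simple random
sample of m APIS subjects joins the feature-selection set as the
*calibration set*; the remaining APIS subjects are the blind *test set*.
m solves (|FS| + m) = ratio × (|APIS| − m) for the target 4:1
calibration:test proportion — interpreted as the ratio of the whole
calibration set to the test set — and is clamped with a warning when the
APIS set is too small. Coefficients are refit on the calibration set only
(the feature set is never reselected); signs are compared against the
selection-time fit and any flip is warned about, since a conserved sign
is the check that the detected effect survived recalibration.

Performance is reported as accuracy, sensitivity (case-positive
convention: the disease-progressed class is the positive class),
specificity, and the rank-statistic AUC (Mann-Whitney with ties counted
one half; the trapezoidal area under the reported ROC curve equals it
exactly). Bootstrap intervals come from `n_bootstrap` = 1,000
class-stratified resamples scored with the *fixed* calibrated model — no
refitting inside resamples — summarised by the mean and the 2.5/97.5
percentiles. Stratification is a deliberate deviation from naive
resampling: sensitivity and specificity are per-class ratios and an
unstratified resample can empty a class. A refit-per-resample variant
exists behind a flag.

The **random-model null** draws `n_random_models` = 1,000 uniformly
random feature sets of the panel's size from the filtered pool, fits each
on the calibration set, bootstrap-evaluates it identically, and reports
the proportion outperforming the panel — separately for bootstrap-mean
accuracy and AUC — plus 2.5/97.5 percentile bands for the density plot.

## The synthetic cohort generator

No public deposit reproduces the motivating data, so `generate_cohort()`
is a first-class, tested module. It emulates exactly the structure the
pipeline exercises:

* class sizes default to 48/98/48 (HC/MCI/AD) and 650 features in
  modality blocks (clinical flags take `binary_fraction` = 10% of
  columns; the continuous remainder splits evenly over MRI volume /
  thickness / surface, PET, and fluid blocks);
* noise features are standard normal within class; a planted feature
  shifts its case-class mean by δ, so its single-feature population AUC
  is Φ(δ/√2) — the closed form used as a test oracle;
* duplicates are ρ·parent + √(1 − ρ²)·noise with ρ = 0.9 by default
  (mirroring reported left/right-hippocampus correlations of ~0.86–0.88);
  the first duplicate parents are the planted features themselves, so
  merging is exercised where it matters;
* binary flags threshold latent normals at 30% prevalence (a typical
  clinical-history flag rate);
* missingness is MCAR per modality, defaulting to 5% (MRI), 10% (PET),
  15% (fluid) and 2% (clinical) — fluid assays are the sparsest source in
  this field, clinical records the densest. MNAR mechanisms are out of
  scope.

What passing tests on these cohorts shows — and does not show: the
pipeline recovers planted additive mean-shift structure under MCAR
missingness and near-duplicate redundancy; real data add non-Gaussian
marginals, inter-modality correlation beyond planted pairs, informative
missingness, and label noise, none of which the generator models.

## Numerical choices

* Logistic fits use iteratively reweighted least squares with step
  halving, so the deviance is non-increasing; convergence when
  max |X′(y − p)| < 1e-8 or the relative deviance change is below 1e-10.
  Weights are clamped at 1e-10 to keep the normal equations solvable.
* Perfect separation is detected from runaway coefficients (|β| > 20 on
  standardized features) or a vanishing deviance; the fit is flagged
  non-converged with a warning and its coefficients are not trusted.
  Singular designs abort naming the collinear feature(s).
* Wald standard errors come from the inverse of X′WX at the optimum;
  coefficient p-values are two-sided normal.
* Wilcoxon screens use the exact null distribution for combined n ≤ 20
  and the tie-corrected normal approximation otherwise; the Bonferroni
  adjustment is min(1, p·m) with m the number of features screened.
* Fold assignments are stratified round-robin deals within class; a fold
  set whose restriction to a model's complete cases leaves a training
  set single-classed is redrawn deterministically (at most 10 attempts,
  then an error).
* One master seed drives everything; each stage derives an offset stream,
  so toggling one stage never perturbs another's randomness, and reruns
  are bit-identical (the pipeline manifest records file checksums to make
  this checkable).

## Problem sizes in the test suite

The shipped tests run the search at reduced scale — typically 100 GA runs
of 50 generations over 600 features and 600 subjects for end-to-end
recovery checks (20 replicates), 1,000 simulated datasets for the IDI
size check, and 200-resample bootstraps with 200 random null models —
sizes chosen so the full suite completes in a few minutes while keeping
every Monte-Carlo margin interpretable. The defaults in
`analysis_spec()` remain the full-scale study values.

## Known limitations

* The calibration set deliberately reuses the feature-selection subjects,
  as the source methodology does; test-set metrics are the only fully
  blind numbers, and the bootstrap intervals on the calibration set
  inherit selection optimism.
* The IDI gate's mild anti-conservatism (above) means the forward walk
  admits a noise candidate slightly more often than α suggests; backward
  elimination compensates but not perfectly.
* Accuracy at a fixed 0.5 threshold is the fitness and reporting metric;
  heavily imbalanced contrasts would reward a threshold or a
  cost-sensitive fitness the package does not currently provide
  (`prob_threshold` is exposed but constant across stages).
* Chromosome size is fixed (default 5); the GA does not search over model
  size — size adaptation happens only through forward selection and
  backward elimination.
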