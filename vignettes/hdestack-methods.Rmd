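---
title: "Methods: diversity-driven stacking with hybrid differential evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity-driven stacking with hybrid differential evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seed-variety identification from non-destructive measurements fuses two
modalities: morphological features extracted from kernel images
(geometry, texture, color — 52 named columns here) and NIR reflectance
spectra (350–2500 nm at 1 nm, 2151 bands). Classes are varieties,
integer-coded `0..K-1`. Single classifiers plateau on such fused,
high-dimensional data; this package implements a stacking ensemble
whose base learners are chosen for being *good but different*, whose
hyperparameters are tuned by a hybrid differential-evolution (HDE)
optimizer, and whose decisions are explained by weighted Shapley
attribution.

## Preprocessing

Spectra are smoothed per sample with a Savitzky–Golay filter
(`sg_smooth()`). Defaults are window 11, polynomial order 2 — standard
NIR practice: the window spans ~11 nm, well below the ~40 nm width of
the reflectance peaks, so peak morphology is preserved while
band-to-band noise is attenuated. Both feature blocks are min–max
normalized (`minmax_normalize()`); ranges are learned on training rows
only, so held-out samples may fall outside `[0, 1]` (they are flagged,
not clipped). Constant features map to 0 by convention. Whether
spectra need min–max at all is debatable (reflectance is already
bounded); we normalize both blocks by default so every fused feature
enters the candidate models on a comparable scale, and the ranges
argument makes the choice reversible. The train/test split
(`split_stratified()`, default 7:3) is stratified by class;
`floor(0.7 * 150) = 105` training kernels per variety.

## Feature selection

Morphological selectors (`morph_select()`) are thin wrappers returning
a top-`k = 15` set: mutual-information ranking (equal-frequency
discretization, 10 bins), recursive feature elimination backed by a
standardized multinomial-logistic fit (dropping the worst ~20% of
survivors per round), and Gini-importance thresholding from a random
forest.

Spectral band selection implements three chemometric algorithms in
full:

* **SPA** (`spa_select()`) builds minimally collinear forward chains by
  successive orthogonal projection and scores every chain prefix with
  a multiple linear regression on one-hot labels over a held-out
  validation split; the (start, size) pair with minimal RMSE wins.
  After autoscaling all columns have equal norm, so by default only
  the `n_starts` largest-norm bands seed chains; `n_starts = NULL`
  tries every band.
* **CARS** (`cars_select()`) runs Monte-Carlo samplings in which an
  inner PLS (on one-hot labels, ≤ 5 components) ranks bands by
  absolute regression coefficient; the retained count follows a
  two-constant exponential decay fixed by its endpoints (all bands at
  the first sampling, two at the last), adaptive reweighted sampling
  draws the survivors, and the subset minimizing 5-fold RMSECV is
  returned.
* **BOSS** (`boss_select()`) draws weighted bootstrap sub-models over
  the surviving bands, scores them out-of-bag, accumulates the
  normalized absolute PLS coefficients of the best tenth into soft
  weights (bands absent from every retained sub-model shrink to zero),
  and returns the bands of the minimal-RMSECV iteration.

The inner regression throughout CARS/BOSS is PLS on one-hot class
indicators — the standard chemometric device when the criterion is
RMSECV; SPA uses plain MLR for its prefix scoring because each
candidate subset is small and already near-orthogonal, making the
validation RMSE of an unregularized fit both meaningful and two orders
of magnitude cheaper than a cross-validated PLS per prefix. Fused
tables are column-wise concatenations (morphological block first) with
modality tags preserved (`fuse_features()`).

## Candidate ranking: diversity + performance

Six candidates are considered: multinomial logistic regression (LR),
decision tree (DT), RBF-SVM, k-NN, Gaussian process (GP) and a
single-hidden-layer MLP. Each is evaluated by stratified 5-fold
cross-validation on the training set; its out-of-fold predictions
feed both the performance metrics and the pairwise diversity measures.

For two classifiers, the 2×2 correct/incorrect contingency counts
`a, b, c, d` yield four pairwise measures: disagreement
`Dis = (b+c)/n`, Q-statistic `Qs = (ad-bc)/(ad+bc)`, kappa
`Ks = (p1-p2)/(1-p2)`, and the phi correlation `Cor`. `Dis` grows with
diversity; the other three measure similarity, so their direction is
reversed (`1 - value`) before aggregation. Undefined pairs (zero
denominators) are dropped pairwise, not model-wise.

The **diversity composite index** of model *x* sums, over the four
metrics, its share of the total pairwise difference mass:
`Dci_x = Σ_t d_{x,t} / Σ_y d_{y,t}`. The denominator is applied per
metric, inside the sum, so the indices sum to `T = 4` across models —
with six candidates the values land in the ~0.4–0.8 range typical of
published tables; `scale = "unit"` divides by `T` for a probability
normalization. The **performance composite index** is the analogous
share sum over accuracy and macro precision/recall/F1. The
**comprehensive score** blends them, `P_x = r·Dci_x + (1-r)·Pci_x`
with `r = 0.5` (diversity and accuracy equally weighted); candidates
are ranked descending with ties broken by higher `Pci`, then name, so
rankings are reproducible. The top-`K` candidates (default `K = 3`)
become the base learners. Macro averaging is used for multiclass
precision/recall (the design is balanced), and F1 is the harmonic mean
of macro precision and macro recall — the same identity the published
per-model tables satisfy.

## The hybrid DE optimizer

Hyperparameters live in a unit hypercube; `param_space()` maps genomes
to mixed assignments (log-affine for scale parameters such as
regularization strengths, rounding for integers, flooring for
categories). The optimizer (`hde_optimize()`) extends canonical
DE/rand/1/bin three ways:

1. **Stage-scheduled multi-strategy mutation.** Generations in the
   first third use `rand1` (exploration), the middle third
   `current_to_best1` (balance), the final third alternates `best1`
   and `best2` by generation parity (exploitation). Boundaries at
   thirds are the natural reading of an initial/intermediate/late
   schedule.
2. **Convergence-adaptive F and CR.** The convergence indicator `c_t`
   is the best-fitness improvement over a 5-generation window,
   relative to the older value; the piecewise rule draws
   `F ∈ {0.2, 0.3, 0.5} + 0.5·U[0,1]` and sets
   `CR ∈ {0.95, 0.9, 0.7}` over the branches `c_t ≤ 0.05`,
   `(0.05, 0.1]`, `> 0.1`. The window-relative definition puts `c_t`
   on the same scale as those thresholds.
3. **Diversity-adaptive inflation.** With population diversity
   `D` (mean pairwise Euclidean distance) and reference `D_max` fixed
   at the initial population's diversity, `F` and `CR` are inflated by
   `ΔF·(1 - D/D_max)` and `ΔCR·(1 - D/D_max)` as the population
   contracts, clamped to `(0, 1.2]` and `(0, 1]`.

The default `adapt_mode = "both"` composes the two mechanisms — the
convergence rule supplies the draw, the diversity term shifts it; the
two rules are presented independently in the source formulation and
their composition is a design choice here (each is also available
alone, and `"none"` gives plain DE with fixed parameters). Selection
is greedy one-to-one; the best-fitness trace is therefore monotone.
A failing objective scores `-Inf` rather than aborting the run.
Everything is reproducible from one integer seed.

The stacking objective (`cv_fitness()`) is the mean stratified-CV
accuracy of the whole stack under the decoded hyperparameters, with
seeded folds so the objective is deterministic. Because each
evaluation refits the full stack per fold, tuning runs in this
package's examples use small populations and budgets (NP ≈ 6–20,
G ≈ 5–15) — adequate for the low-dimensional spaces involved.

## Stacking

Base learners are fitted on the full training set; the meta-learner —
multinomial logistic regression, chosen because its coefficients
support weight extraction — is fitted on out-of-fold class
probabilities (`oof_meta_features()`), so no row is ever predicted by
a model trained on it. The GP contributes one-hot probabilities of its
predicted class because this implementation's multiclass probability
coupling is unreliable (the stated convention for learners without
usable probability output). Per-base weights are the mean absolute
meta-coefficient over each learner's probability columns, normalized
to sum to one. `ensemble_size_sweep()` traces test performance as the
top-K grows, reproducing the rise-then-fall pattern expected when
weaker or redundant learners join.

## Weighted SHAP explanation

`shap_values()` computes interventional Shapley values against a
background sample (a k-means summary of the training data, default 50
centers). Two estimators are provided: exact subset enumeration for
small feature counts (≤ 10 by default), and permutation telescoping
otherwise — for each sampled feature ordering the marginal
contributions telescope from the background mean to `f(x)`, so
additivity (local accuracy) is exact *by construction* in both modes;
sampling error affects only the split between features. The stack
explanation (`stack_shap()`) multiplies each base learner's tensor by
its meta-weight and sums — this explains the weight-mixture surrogate
of the stack, not the exact meta-learner composition; the surrogate
is the object the weighted-aggregation procedure defines, and the
reconstruction `base + Σφ` is checked against the surrogate's
prediction in the tests. Multiclass explanations are per-class
tensors; the summary defaults to each sample's predicted class.

## The synthetic data generator

No real multimodal seed dataset ships with the package; the generator
(`sim_seed_dataset()`) emulates its structure so every stage is
testable:

* **Spectra**: a shared smooth base curve — linear baseline plus
  Gaussian bumps (width ~40 nm) at peaks 863/1105/1295/1680/2015 nm
  minus bumps at valleys 980/1175/1450/1780/1915 nm — with
  class-specific offsets and slopes (sd `class_shift_sd`),
  class-specific peak-amplitude scalings (sd `3·class_shift_sd`,
  giving band selectors localized signal), and i.i.d. per-band noise
  (sd `noise_sd`).
* **Morphology**: 52 columns named after the field's feature families
  (`E`, `r`, `contrast`, `hist0`, `a_dev`, …); the first
  `n_informative = 10` carry class-dependent means (standardized
  separation `morph_effect_size`), the rest are noise; all columns get
  deliberately heterogeneous scales (log-uniform over five decades) so
  normalization is genuinely exercised.

Defaults (`n_classes = 11`, `n_per_class = 150`,
`class_shift_sd = 0.002`, `noise_sd = 0.01`,
`morph_effect_size = 0.45`) were fixed once so the synthetic study
reproduces the qualitative regime reported for real maize kernels:
candidate accuracies spread over roughly 60–90% on fused selected
features, morphology alone far weaker than spectra alone, and a
stacking gain over the mean base learner. The generator does **not**
model instrument physics, scattering, inter-annual variation or
class-imbalance; passing tests therefore demonstrate correctness of
the algorithms under a realistic covariance structure, not performance
claims about any real instrument.

All randomness descends from one integer seed via fixed offsets;
regeneration is bit-identical.

## Numerical choices and degenerate inputs

* Pairwise contingency counts are stored as doubles: the correlation
  denominator `(a+b)(a+c)(c+d)(b+d)` overflows 32-bit integers at
  n ≈ 10³.
* Zero-denominator pairwise metrics return `NA` and are excluded
  pairwise; an all-equal metric (zero total difference mass) is
  skipped with a warning.
* SPA treats residual norms below 1e-8 as exhausted (collinearity
  elimination); duplicated columns can never both enter a chain.
* CARS forces at least two retained bands and stops early if the pool
  collapses; BOSS returns the best iteration seen when soft shrinkage
  empties the pool.
* DE genomes are clipped to `[0, 1]` after mutation and crossover;
  categorical decoding clamps `floor(g·k)` at the last level so
  `g = 1` is valid.
* Ranking ties break by `Pci` then lexicographic model name.

## Problem sizes used in tests and the acceptance script

The test suite and `scripts/acceptance.R` run the full study at
11 classes × 150 kernels with the 2151-band grid for generation and
preprocessing, and fuse 15 selected morphological features with a
band subset for model fitting; selector benchmarks use 120-band
spectra-like fixtures, and optimizer benchmarks use enumerable
discrete spaces and low-dimensional continuous problems. These sizes
were chosen as the smallest at which every contract under test is
meaningfully exercised.

## Known limitations

* The Gaussian-process learner returns hard class probabilities (see
  above), which slightly coarsens its meta-features.
* The aggregated SHAP explanation covers the weight-mixture surrogate,
  not the meta-learner's exact composition of base probabilities.
* `cv_fitness()` is expensive by construction (a full stack refit per
  fold per evaluation); tune on subsets or with small budgets.
* Published composite-index magnitudes depend on a normalization the
  source specification leaves ambiguous; this implementation fixes one
  reading (per-metric shares) and treats orderings, not magnitudes, as
  the reproducible contract.
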