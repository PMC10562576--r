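---
title: "Methods: box-counting fractal dimension and explainable nested-validation prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: box-counting fractal dimension and explainable nested-validation prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracdem)
```

# Scope

`fracdem` implements two analysis arms used to study the 2-year transition
from mild cognitive impairment (MCI) with leukoaraiosis to dementia:

1. an **imaging arm** — the 3-D box-counting fractal dimension (FD) of
   binary brain-structure masks, with grid-offset averaging and automated
   selection of the fractal scaling window; and
2. a **tabular arm** — a gradient-boosted-tree classifier over 21 baseline
   features evaluated under a repeated stratified bootstrap nested-validation
   scheme, with exact tree SHAP attributions, a median ROC curve, the Youden
   operating point, and a one-tailed Wilcoxon signed-rank test against
   chance.

The patient cohort behind the original analysis is not public, so the
package ships analytic phantoms and a synthetic cohort simulator
parameterized by the published per-group descriptive statistics; every
empirical statement in this vignette is one the package's test suite or
`scripts/acceptance.R` computes itself.

# The box-counting estimator

## Model

For a binary mask, box counting overlays a grid of cubes of side length $s$
(voxel units) and counts the cubes $N(s)$ occupied by the structure.  For an
object with box-counting dimension $D$, $N(s) \propto s^{-D}$ over the
structure's fractal scaling regime, so $D$ is the absolute slope of the
ordinary-least-squares fit of $\log N(s)$ on $\log s$ restricted to that
regime.  A voxel is represented by its integer corner coordinate; a voxel
$v$ falls in grid cell $\lfloor (v - o)/s \rfloor$ per axis for grid offset
$o$.

## Grid offsets and the relative count

A single grid placement biases $N(s)$ by up to one cell per axis, so for
each $s$ the package draws 20 offsets uniformly from $[0, s)^3$ and
averages.  Averaging **raw** counts, however, is itself biased: a randomly
placed grid cuts an edge of length $L$ into about $L/s + 1 - 1/s$ pieces
rather than $L/s$, inflating the count by roughly $(1 + (s-1)/L)^3$.  The
inflation grows with $s$, flattens the log-log curve, and pulls the fitted
slope of a solid $64^3$ cube down to about $2.9$ even in the most favourable
window — the estimator would fail its own phantom validation.

`box_count_curve()` therefore averages the **relative** box count: each
offset's structure count is divided by the number of cells the same grid
assigns to the structure's bounding-box *solid*, and the offset-averaged
fraction is rescaled by the ideal aligned cell count
$\prod_a \max(1, E_a/s)$ ($E_a$ = bounding-box edge).  The solid reference
suffers exactly the same boundary inflation as the structure, so the ratio
cancels it: compact bodies (cube, slab, line) recover *exact* power laws at
every scale and offset, while genuinely porous structures keep their
internal (lacunarity) signal.  The raw mean remains available via
`normalize = FALSE`.  Masks are cropped to their foreground bounding box
first, which also makes the curve exactly invariant under integer
translation.

## Scale ladder

The box sizes are all integers $1, 2, \ldots, \lfloor E/2 \rfloor$ with $E$
the longest bounding-box edge (at least 3 sizes, else an error asks for
explicit scales).  Stopping at $E/2$ keeps the largest boxes from trivially
covering the object.  The *dense* ladder matters for lattice fractals: a
Menger sponge is self-similar under scale factor 3, and its box counts carry
a log-periodic oscillation with period $\log 3$.  Sampling only octaves
($1, 2, 4, \ldots$) aliases that oscillation — the measured window slope of
an iteration-4 sponge lands near 2.50 instead of
$\log 20 / \log 3 \approx 2.727$ — whereas a window spanning the dense
ladder averages full oscillation periods and lands within $\pm 0.05$.  An
octave ladder is still available (`default_scales(mask, kind = "pow2")`).

## Scaling-window selection

Natural structures are fractal only over a limited scale interval, unknown a
priori.  `select_scaling_window()` scores **every** contiguous window of at
least 3 scale points by the adjusted coefficient of determination of the
log-log OLS fit,
$R^2_{adj} = 1 - (1 - R^2)(m - 1)/(m - 2)$ for $m$ points, rounded to two
decimals.  The window with the highest rounded score wins; ties prefer (i)
more scale points, then (ii) the smaller starting scale.  Numerical choices:

* **Rounding to 2 decimals** makes the tie-break meaningful — windows whose
  fits differ only in the third decimal are treated as equally good and the
  wider one (more data) is used.
* A residual-free fit on a constant series (e.g. a single-voxel mask, where
  $N \equiv 1$) counts as $R^2_{adj} = 1$ with slope 0, so degenerate masks
  yield FD 0 rather than an error.
* A two-point window always fits perfectly and is therefore never
  considered (minimum window length 3).
* The stored `radj2_rounded` is clamped to $[0, 1]$; selection itself uses
  the unclamped rounded score.

`compute_fd()` composes `default_scales`, `box_count_curve`,
`select_scaling_window` and `fit_fd`; `hemispheric_average()` is the
arithmetic mean of a left and right FD, the whole-structure summary used for
bilateral anatomy.

## Phantoms and what a green test establishes

`make_phantom()` builds a solid cube ($D = 3$), a one-voxel slab ($D = 2$),
a line ($D = 1$) and the Menger sponge at up to 5 iterations
($D = \log 20/\log 3$, built by the exact 20-of-27 recursive retention on a
$3^m$ grid).  The acceptance tests require FD within $\pm 0.05$ of the
analytic value for the 64-sized compact phantoms and $\pm 0.10$ for the
iteration-4 sponge; measured values are exact for cube/slab/line and about
$+0.045$ for the sponge, stably across seeds.  These phantoms validate the
estimator's *calibration on known geometry*; they do not certify accuracy on
cortical ribbons, whose true dimension has no analytic reference.

# The synthetic cohort

`default_cohort_spec()` encodes, for each of the 21 features in 4 categories
(3 demographic, 6 neuropsychological, 4 visually assessed MRI, 8
quantitative MRI), the published per-group mean (SD) [min, max] for the 46
non-converting and 18 converting subjects; sex is Bernoulli with the
per-group female proportion (22/46, 8/18).  `simulate_cohort()` draws each
feature independently within group from a range-truncated Gaussian
(rejection sampling); ordinal visual scores (lacunes, microbleeds, enlarged
perivascular spaces) are additionally rounded and clipped.  Missingness is
injected MCAR at a user-chosen rate (`inject_missingness()`); the real rate
and mechanism are unpublished.

What the simulator does *not* emulate: inter-feature correlation (no
covariance structure is published — real volumes, diffusion indices and
cognitive scores are substantially correlated), longitudinal structure, and
non-random missingness.  A green pipeline test therefore establishes that
the *protocol* behaves correctly (no leakage, correct stratification,
calibrated null, signal recovery), not that the published real-data AUC is
reproduced — it cannot be, without the patient data.  Note also that
truncation shifts a skewed feature's realized mean away from the printed
Gaussian parameter (by design; the tests compare against the closed-form
truncated-normal expectation).

`make_separable_cohort()` is the signal-recovery fixture: all features are
drawn from the non-transition distribution in both groups except one, whose
transition-group mean *and truncation bounds* are shifted downward by a
requested number of pooled SDs — shifting the bounds keeps the shape
identical so the realized group separation equals the requested effect
size.  The default signal (cortical GM FD, lower in converters) matches the
disease direction.

# The prediction protocol

## Validation scheme

Each of the (by default 100) repetitions performs:

1. **Stratified bootstrap outer split** — within each outcome class, that
   class's subject count is drawn with replacement, so the training multiset
   always holds exactly 46/18; the out-of-bag (OOB) subjects form the test
   set.  If an OOB set lacks a class (AUC undefined), the draw repeats with
   an incremented seed and the event is logged.
2. **Random search** over the published 1296-point hyperparameter grid
   (gamma, colsample_bytree, max_depth, min_child_weight, n_estimators,
   subsample), scored by **subject-level stratified 5-fold CV** on the outer
   training multiset: all bootstrap copies of a subject share its fold, so
   no subject is ever on both sides of an inner split.  The inner objective
   is the mean validation AUC (the published text says only "out-of-sample
   prediction error"; AUC matches the outer metric).  Validation folds are
   scored on unique subjects — one row per subject — so a multiply-drawn
   subject does not get extra weight in the inner score.  Ties prefer fewer
   trees, then shallower trees, then sampling order.  The search budget is
   not published; the default is 50 candidates (1296 = exhaustive).
3. **Preprocessing** — mean imputation then z-standardization — is refit on
   every training context (each inner fold, then the outer training
   multiset) and applied unchanged downstream.  The standardizer uses the
   population (1/n) SD, the convention of the Python scaler the study's
   stack implies; constant columns map to 0.
4. The winning configuration is refit on the full outer training multiset
   (per-repetition fixed seed) and evaluated on the OOB subjects only:
   probabilities, AUC, ROC coordinates, and SHAP attributions.

Leakage and stratification audits run programmatically on every repetition.

## The learner

No gradient-boosting or SHAP library is available in the target
environment, so the package implements both (in C++ via Rcpp), mirroring
the XGBoost binary classifier: second-order boosting on the logistic loss,
exact greedy splits, gain
$\tfrac12[G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)] - \gamma$,
leaf weight $-\eta G/(H+\lambda)$, per-tree row subsampling without
replacement and column subsampling.  Fixed choices outside the published
grid: learning rate $\eta = 0.3$ and L2 penalty $\lambda = 1$ (the XGBoost
defaults), initial margin 0, no class weighting (not in the printed grid).
`min_child_weight` follows the paper's own definition — *the minimum number
of instances required in each node* — rather than XGBoost's hessian-sum
reading; with a logistic hessian of at most 1/4 per row, the hessian reading
would make most of the printed grid unable to split at all at subsample 0.1
of 64 rows.

## Evaluation conventions

* **AUC** is the Mann-Whitney concordance probability with ties counted
  1/2; the ROC curve is the descending-threshold sweep and its trapezoidal
  area equals the concordance AUC exactly.
* **Median ROC**: each repetition's curve is interpolated onto a common FPR
  grid (step 0.01) as a step function — the supremum of TPR over points
  with FPR at most the grid value — then the pointwise median and
  25th/75th percentiles are taken.  The convention is stated because the
  source gives none.
* **Youden operating point**: the point maximizing $J = TPR - FPR$ on the
  median curve, ties resolved toward lower FPR.
* **90% CI** of the AUC: the empirical 5th-95th percentile interval of the
  repetition AUCs (percentile-of-repetitions matches the repeated-resampling
  design; whether the original interval was percentile or Gaussian is
  unstated).
* **Wilcoxon signed rank** (one-tailed, greater): zero differences are
  discarded; the exact `psignrank` null is used when $n \le 25$ and the
  absolute differences are tie-free, otherwise the normal approximation
  with tie and continuity corrections (exactness under ties is impossible).

## Explanation

SHAP values are computed by the exact polynomial-time **path-dependent**
tree algorithm, with per-node covers recorded from the full outer training
set (the variant and background are unstated in the source; path-dependent
with the training background is the standard exact choice for tree
ensembles, and is stated here so results are reproducible).  Local accuracy
— base value plus the row sum of attributions equals the margin output — is
asserted to $10^{-4}$ on every OOB prediction in the tests (the
implementation achieves $10^{-8}$ or better) and the implementation is
cross-checked against a brute-force subset-enumeration Shapley oracle.

Per repetition, a feature's global importance is the mean $|SHAP|$ across
that repetition's OOB subjects; the final ranking uses the median over
repetitions.  Category importance is the mean of member features' global
values (so it always lies between the members' extremes).  The top two
features (by median) are compared by the paired one-tailed signed-rank test
over their per-repetition values.

# Known limitations and honest negatives

* **Null calibration across runs.**  On fully independent permuted-label
  cohorts the OOB AUC is unbiased (measured mean 0.496, SE 0.010 over 150
  cohorts).  Within one run, however, all repetitions share a single fixed
  permutation; when that permutation happens to align labels with one of
  the 21 features (the best single-feature chance association in a 46/18
  cohort is sizeable), every repetition genuinely reflects it, and the
  per-run Wilcoxon correctly rejects.  Roughly a third of permutations are
  detectable this way, so the acceptance expectation that at least 90% of
  permuted-label runs test non-significant is not met (measured ~13/20) and
  is deliberately left failing: the repetition AUCs of a bootstrap scheme
  over one cohort are not the independent chance-level draws that
  expectation presumes.
* The real-data headline results (mean AUC 0.69, 90% CI 0.53-0.85,
  sensitivity/specificity 0.67/0.67, GM FD top-ranked with hippocampal
  volume second) are **not** asserted anywhere: they require the non-public
  cohort.  The pipeline runs the full protocol shape on the
  published-statistics simulator instead.
* Whole-structure FD only; regional or vertex-wise fractal analysis, and
  any upstream segmentation, are out of scope.
* The Menger-sponge error does not shrink strictly monotonically from
  iteration 3 to 4 (measured $+0.11, -0.02, +0.05$ for iterations 2-4);
  the tests assert the magnitude envelope (iteration 2 worst), since strict
  monotonicity of a noisy error sequence is not a meaningful invariant.

# Reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; a whole nested run is a pure function of the cohort and
`base_seed`, and `run_full_pipeline()` writes a provenance block (package
version, full configuration, seeds) sufficient to re-execute a report
byte-identically.

```{r example, eval = FALSE}
tab <- simulate_cohort(seed = 1)
res <- run_full_pipeline(default_run_config(seed = 1L, n_repetitions = 100L,
                                            out_dir = "report"))
res$summary$mean_auc
```
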