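---
title: "Neural additive models for interpretable blood-panel classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural additive models for interpretable blood-panel classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hemanam` fits a neural additive model (NAM) for binary diagnosis from a
routine blood panel. Each feature $x_i$ is processed by its own small
feed-forward subnetwork $f_i$ (two ReLU hidden layers, by default 64 and 32
units, with inverted dropout at rate 0.2 during training), and the prediction
is assembled additively on the logit scale:

$$\mathrm{logit}\, P(y = 1 \mid x) \;=\; \beta_0 + \sum_{i=1}^{p} f_i(x_i).$$

Additivity is the interpretability mechanism: the contribution of feature
$i$ to any prediction is the scalar $f_i(x_i)$, exactly, with no
approximation. The package computes explanations as centered contributions
$\phi_i(x) = f_i(x_i) - \bar f_i$, where $\bar f_i$ is the mean of $f_i$
over a reference population (by default the training set). Then
$\text{base} + \sum_i \phi_i$ reproduces the logit exactly for every sample,
and for additive models these $\phi_i$ coincide with interventional Shapley
values — a fact the test suite verifies against a brute-force
coalition-enumeration oracle for up to six features.

A positive $\phi_i$ pushes the prediction toward the case class (label 1),
a negative one toward control. Attributions live on the logit scale, where
they are additive; probabilities are obtained through the sigmoid at the
end.

## Training protocol

`nam()` optimizes binary cross-entropy with minibatch Adam. The defaults are
the protocol commonly used for this kind of tabular clinical classifier and
are all exposed as arguments:

| parameter | default | meaning |
|---|---|---|
| `hidden` | `c(64, 32)` | hidden-layer widths of every subnetwork |
| `dropout` | 0.2 | inverted dropout after each hidden layer (training only) |
| `learning_rate` | 0.001 | initial Adam step size |
| `weight_decay` | 1e-5 | L2 penalty, applied by the optimizer to weight matrices only |
| `max_epochs` | 150 | hard cap on training epochs |
| `patience` | 20 | early stopping after this many epochs without monitor improvement |
| `scheduler_patience`, `scheduler_factor` | 10, 0.5 | reduce-on-plateau learning-rate halving |
| `batch_size` | 64 | minibatch size (not dictated by the protocol; 64 is a conventional choice) |

Weights use He-style initialization (variance $2/\text{fan-in}$, the
appropriate scaling for ReLU units) with zero offsets; the initialization
scheme is a package choice and is recorded in the model object. An
"improvement" of the monitored quantity must exceed `1e-6` so that floating
noise cannot reset the patience counters. The best-epoch weights are
restored when training stops.

Two monitoring conventions circulate for this protocol: early stopping on
held-out *accuracy* computed on the final test set, and early stopping on
*validation loss* with best-weight restoration. The first leaks the test set
into model selection, so the package defaults to the defensible variant: the
monitor is the binary cross-entropy on a 10% stratified carve-out of the
training data (`monitor = "val_loss"`, `val_fraction = 0.1`). For literal
replication of the leaky variant, pass the test set via `validation =
list(x = ..., y = ...)` and set `monitor = "val_accuracy"`.

Standardization is Z-scoring with population standard deviations (divisor
$n$, the convention of common machine-learning scalers), fitted on the data
given to `nam()` — never on held-out rows — and stored in the model so that
`predict()` accepts raw-scale tables.

## The synthetic cohort generator

The deposited clinical dataset the pipeline targets cannot be bundled, so
the package ships a generator whose cohorts have the statistical structure
the analysis assumes, with a *known* additive ground truth. It emulates:

* **23 panel features** (age plus 18 complete-blood-count measures plus the
  four derived indices NEU/LY, PLT/LY, MPV/LY, LY/MO). Counts and indices
  get log-normal marginals calibrated so the control-group median and IQR
  match published control-group descriptive statistics for this panel
  (e.g. WBC median 7.5, IQR 2.282; the basophil column, absent from the
  published table, uses typical clinical values, median 0.03 and IQR 0.025).
  Age is truncated normal (59.17 ± 10.851 on [20, 82]). Marginals are
  coupled through a Gaussian copula.
* **A correlated red-cell block**: RBC, HGB, HCT, MCV, MCH and MCHC share a
  latent Gaussian factor with loading 0.7, mimicking their physiological and
  mathematical coupling.
* **Exact ratio columns**: the four derived indices are computed as
  elementwise quotients of their sampled components, never sampled
  independently.
* **A planted additive signal**: labels are drawn
  $y \sim \mathrm{Bernoulli}\big(\sigma(\sum_i g_i(z_i) + b_0)\big)$, where
  $z_i$ are population-standardized features (closed-form moments per
  marginal family) and the $g_i$ are parametric shapes: a logistic ramp on
  NEU, a linear shape on WBC, a logistic ramp on RDW-CV, a linear shape on
  BA, and a quadratic (U-shaped) effect on LY, in descending strength, with
  zero shapes on the remaining 18 features. Shapes act on standardized
  features so effect sizes are scale-free. The intercept $b_0$ is calibrated
  by bisection so the cohort's mean event probability matches the target
  prevalence 477/981 to within 0.01 (no closed form exists for arbitrary
  shape sets).

Design choices a reader may want to audit:

* **Why exactly five active features?** The recovery tests ask whether
  training recovers the planted shapes and ranks. Keeping the active set
  sparse and well separated in effect size makes that question well-posed;
  real panels certainly carry diffuse signal across many correlated
  features, which this generator deliberately does not emulate.
* **Why a quadratic shape on LY?** Because the ratio columns are exact
  quotients, any log-linear signal on a ratio component is not identifiable:
  a term $c\log(\mathrm{NEU/LY}) = c\log \mathrm{NEU} - c\log \mathrm{LY}$
  can be absorbed by the NEU/LY subnetwork with exact compensation inside
  the NEU and LY subnetworks, leaving the likelihood unchanged. Curvature is
  what the data can pin down, so the planted LY effect is curvature-dominant
  (clinically a U-shape: both lymphopenia and lymphocytosis deviate from a
  healthy profile). NEU keeps a monotone ramp — a non-monotone neutrophil
  effect would be clinically absurd — which means a fraction of the NEU
  signal *can* migrate into the NEU/LY subnetwork during training. This is a
  real property of additive models fitted to panels that include derived
  ratios (published importance tables for this model family show the same
  phenomenon, with NEU/LY ranking near the top), not an artifact of the
  generator; the limitations section returns to it.
* **Effect scale.** Amplitudes were fixed once so that the *oracle*
  classifier — the true additive logit — attains roughly 0.91 accuracy and
  0.97 AUC at the default prevalence, the performance regime reported for
  real AMI blood-panel cohorts. The trained NAM typically lands 2–4
  accuracy points below the oracle.
* **Gender.** The deposited dataset carries a 0/1 gender column, but the
  reference architecture is explicitly a 23-input model whose input list
  excludes gender, so the generator does not simulate it. `read_cohort()`
  accepts tables with extra columns, so real-data replication is unaffected.

## Evaluation and calibration

Threshold metrics (accuracy, balanced accuracy, F1, MCC, sensitivity,
specificity, PPV, NPV, LR+, LR−) are computed from the confusion matrix at
threshold 0.5, with a score exactly at the threshold counting positive; the
threshold convention is a package decision and is configurable. Undefined
quotients (LR+ when specificity is 1, PPV with no predicted positives)
propagate as `NA`, never as 0 or infinity. ROC AUC uses the rank-statistic
(Mann–Whitney) formulation with ties contributing 1/2.

Confidence intervals are percentile bootstrap: resample (probability, label)
pairs with replacement, recompute the metric, take the
$(1 \pm \text{level})/2$ quantiles. The percentile method (rather than BCa)
is the simplest faithful reading of "bootstrap resampling with 1000
iterations"; iterations where a metric is undefined are dropped and counted.
The test suite checks the implementation against an independent seeded
re-implementation and verifies nominal coverage on a known-accuracy
classifier.

Calibration reports use equal-width probability bins (default 10). The
package defines **calibration deviation** as the *unweighted* mean absolute
gap between mean predicted probability and observed event frequency over
non-empty bins; the count-weighted version (expected calibration error) is
available via `weighted = TRUE`. The Brier score is
$\frac1n\sum (p_i - y_i)^2$.

## Pipeline order and augmentation

Bootstrap augmentation (doubling a table by appending a bootstrap resample
of itself) is supported in two positions. The default
(`augment = "train"`) doubles only the training split, after the stratified
80/20 split, which is leakage-safe. The literal augment-then-split order
(`augment = "pre-split"`) is also available for replication; it lets
resampled duplicates straddle the split, so `run_experiment()` emits an
explicit leakage warning when it is used. Stratified splitting apportions
per-class test counts by largest remainder (ties to the larger class), which
reproduces balanced class proportions deterministically; within-class
selection is uniform under the given seed.

## Numerical choices

* Probabilities are clipped to $[10^{-7}, 1 - 10^{-7}]$ inside the
  cross-entropy only; predictions themselves are never clipped.
* The logit is *computed as* $\beta_0 + \sum_i f_i$, so the additivity
  identity holds bit-for-bit rather than to a tolerance.
* Dropout is inverted (kept units scaled by $1/(1-\text{rate})$), so
  evaluation needs no rescaling and is fully deterministic.
* Every stochastic step (initialization, validation carve-out, shuffling,
  dropout masks, bootstrap resampling, cohort generation) is governed by an
  explicit seed; identical configurations reproduce identical artifacts
  bit-for-bit.
* Constant training columns make Z-scoring ill-defined and are a hard
  error, as are missing values (the target datasets have none; imputation
  is out of scope).

## Problem sizes used by the test suite

The bundled tests train the default architecture on cohorts of n = 2000
(three seeds) for recovery checks, n ≈ 1200 for the null control, and
n = 981 — the deposited-cohort size — for the end-to-end replication
protocol; bootstrap checks use 200–1000 iterations. These sizes were chosen
so the planted effects are comfortably estimable while the whole suite stays
quick on a laptop.

## Known limitations

* **Ratio-column identifiability.** As discussed above, additive credit can
  legitimately migrate between a component (NEU, LY) and the derived ratios
  that contain it. Global importance rankings on panels that include exact
  ratio columns should therefore be read with the component/ratio family
  pooled in mind; the package reports both the NAM-intrinsic importance
  (normalized mean |centered $f_i$|) and the attribution-based importance,
  which rank identically by construction.
* The generator reproduces marginals and one correlation block, not the
  full joint distribution of a real panel; passing recovery tests on
  synthetic cohorts shows the estimator works where its assumptions hold,
  not that real AMI data satisfies them.
* The NAM assumes additive, interaction-free effects. Correlated inputs
  (the red-cell block, WBC and its differentials) can redistribute
  importance among themselves without changing predictions.
* No outlier handling, no imputation, no categorical encodings beyond 0/1
  columns; benchmarking against tuned tree ensembles or kernel machines is
  out of scope (a plain logistic baseline is included for sanity contrast
  only).
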