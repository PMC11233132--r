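---
title: "Testing selective recruitment of the cerebellum with task-invariant connectivity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing selective recruitment of the cerebellum with task-invariant connectivity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inferential problem

The cerebellar BOLD signal is dominated by mossy-fiber input, which largely
carries neocortical activity. Cerebellar activation during a task therefore
does not, by itself, show that the cerebellum contributes to that task: the
activity could be the passive transmission of neocortical activity through
fixed anatomical connections. `cbrecruit` implements the analysis that
separates these possibilities. A *task-invariant connectivity model* — a
fixed linear mapping `Y = X W` from cortical parcel activity to cerebellar
voxel activity, estimated on an independent multi-task battery — serves as
the null model of fixed transmission. If cortical input to the cerebellum is
*gated* (upregulated when cerebellar computation is needed), the observed
cerebellar activity for the gated conditions will systematically exceed the
model's prediction. The package estimates the connectivity model, transfers
it to new subjects and conditions, rescales predictions per subject, and
tests the signed residuals.

## The model and its estimation

For each subject, task activity is summarized as condition-by-unit matrices
of normalized GLM coefficients (betas divided by the residual
root-mean-square of the time-series fit, i.e. by the residual standard
deviation per unit). Cortical vertices are averaged within parcels; parcel
id 0 is reserved for unassigned vertices and always excluded. Because rest
is an implicit baseline of the first-level GLM, it is appended to both the
cortical and cerebellar matrices as a row of exact zeros. This anchors
everything at the origin, and consequently *no intercept is used anywhere*:
not in the connectivity fits and, by default, not in the prediction
rescaling.

Connectivity weights solve penalized least squares with two penalties:

* ridge: `argmin ||Y - XW||_F^2 + lambda ||W||_F^2`, solved exactly via the
  normal equations `(X'X + lambda I) W = X'Y`;
* lasso: `argmin 0.5 ||Y - XW||_F^2 + lambda ||W||_1`, solved per target
  column by cyclic coordinate descent on the Gram matrix with pathwise
  continuation (a geometric penalty path from `lambda_max` with warm
  starts).

Penalty values are only meaningful together with the objective convention,
so models always record their `lambda` alongside the method. Predictors are
not standardized before fitting — the inputs are already normalized
activity estimates — which keeps `lambda` interpretable on that scale.

The penalty is tuned by 5-fold cross-validation over condition rows
(seeded, deterministic). Accuracy is the convention used throughout:
the Pearson correlation between predicted and observed response profiles
per target unit across held-out conditions, averaged over units (zero
variance units are skipped and counted). Ties between penalties are broken
toward the larger penalty. Group models are unweighted elementwise means of
subject models.

### Numerical notes on the lasso

Coordinate descent satisfies a per-coordinate Karush-Kuhn-Tucker check
(default tolerance `1e-8`). Training designs in the transfer setting are
wide (more parcels than conditions), so the Gram matrix is singular and the
optimizer's tail can become arbitrarily slow, occasionally cycling among
near-optimal supports. Three safeguards keep the solution exact without
changing the objective: the compiled inner loop refreshes the gradient
exactly at fixed intervals (floating-point drift otherwise masks
convergence), a primal active-set *polish* solves the stationarity system
of the current signed support exactly (dropping sign-flipped or
inconsistent coordinates, admitting the worst violating inactive
coordinate), and a cold restart covers warm starts trapped in a bad
support. Fits that still cannot meet the tolerance raise an error reporting
the worst KKT violation rather than returning a silently inexact solution.

## The selective-recruitment statistic

Connectivity weights estimated on other subjects (and other scanners)
predict regional activity only up to scale, because measurement
signal-to-noise differs between datasets. Following the analysis the
package implements, each subject's predicted ROI profile is regressed onto
the observed profile with a through-origin regression that includes the
rest point (0, 0): `slope = sum(pred * obs) / sum(pred^2)`. The signed
residual `obs - slope * pred` per condition is the test statistic. Key
properties, each asserted by tests:

* residuals are orthogonal to predictions within subject (`sum(pred * resid)
  = 0` to 1e-10, rest included);
* residuals are invariant to rescaling the predictions (the slope absorbs
  the factor) and scale linearly with the observations;
* the within-subject mean residual need *not* be zero — through-origin
  regression does not center residuals, which distinguishes it from the
  free-intercept mode.

A free-intercept mode exists because the wording of the source analyses
differs between the motor and working-memory datasets; through-origin with
rest included is the default, and `r_squared` is computed uncentered in that
mode (so it stays in [0, 1]) and centered in the free-intercept mode.
Nonpositive slopes are flagged, not rejected.

Rest anchors the fit but is excluded from inference. The residual table
(subjects x conditions) is submitted to a one-way repeated-measures ANOVA;
when the design declares a factorial crossing, additionally to a
fully-within-subject factorial ANOVA in which every effect is tested
against its own effect-by-subject interaction (`df_den = df_num * (S - 1)`,
no sphericity correction). Directed post-hoc contrasts use one-sided paired
t-tests by default — selective recruitment predicts positive residual
differences — with a two-sided option, and no multiplicity adjustment by
default. Degenerate cases are explicit: a zero error SS yields `F = Inf`
with `p = 0` and a flag; zero-variance paired differences yield `t = 0` or
`t = +/-Inf` with a flag.

The ANOVA is computed directly from the balanced-design sums of squares
(inclusion-exclusion over marginal means), which keeps the SS partition,
per-effect error terms, and degenerate branches fully specified; the test
suite verifies exact agreement with `stats::aov` error strata and with a
brute-force oracle.

## What the synthetic generator emulates

`simulate_dataset()` draws shared task loadings `T` (conditions x rank) and
parcel loadings `B`, a sparse nonnegative true weight matrix `W_true`, and
per subject

```
X_s = m + (T + jitter_s) B + noise,   Y_s = gate * (X_s W_true) + noise
```

with `gate = 1 + g` on gated condition rows restricted to the ROI voxels.
Training conditions (the stand-in for the independent multi-task battery)
are never gated; the test conditions are a disjoint set, mirroring the
transfer setting. Rest rows are not generated — the pipeline appends exact
zeros, as with real data.

Defaults define the reference study conditions: 8 subjects, 30 training and
10 test conditions, P = 40 parcels, Q = 20 voxels, sparsity 0.7, SNR 10,
subject jitter 0.2, gating on the first 3 test conditions, ROI = the gated
half of the voxels. Choices worth explaining:

* **`snr` is an amplitude ratio** (signal SD over noise SD, the tSNR-style
  convention common for fMRI), so SNR 10 means noise SD 0.1 against
  unit-variance signal.
* **`task_rank` defaults to the number of training conditions.** A
  multi-domain battery is designed to span as many distinct activity
  dimensions as it has conditions. This matters for identifiability: with
  fewer effective task dimensions than parcels, connectivity weights are
  only identifiable within the subspace the activity spans, and weight
  recovery degrades no matter the estimator — a regime the parameter lets
  you study deliberately.
* **`task_activation_mean = 1`**: task conditions activate cortex above the
  rest baseline. This gives predicted ROI activity a consistent positive
  sign, which is what makes gating amplification detectable as *positive*
  residuals and what anchors the through-origin rescaling; with zero-mean
  activity the sign of a gated condition's residual would follow the random
  sign of its prediction.
* **`W_true` sparse and nonnegative**: mossy-fiber input is excitatory and
  convergence is structured; sparsity is what makes the wide (N < P)
  estimation identifiable for the lasso. This is a modeling convenience for
  testability, not a biological claim.

`recovery_experiment()` therefore defaults to the lasso: ridge estimates
are confined to the row space of each subject's activity and cap well below
full weight recovery in the wide regime, while the sparsity-exploiting
estimator recovers `W_true` essentially completely at the reference
configuration (mean per-voxel correlation ≥ 0.95, checked at a fixed seed).
Its label-shuffled control refits with the *same* per-subject penalty on
permuted condition rows, so only the cortex-cerebellum correspondence is
destroyed. Lasso fits inside this experiment use a KKT tolerance of 1e-6 —
looser than the solver default because the wide designs slow the optimizer
tail, and a 1e-6 gap perturbs weights far below the quantities compared.

`calibration_experiment()` and `power_experiment()` run the full residual
pipeline on thousands of fresh datasets (replicate seeds derived from the
config seed by fixed offsets). They predict with the *true* weights: the
point is to validate the residual statistic, and a per-replicate estimated
model would inject condition-consistent estimation error shared across
subjects — a property of model quality (covered by the recovery
experiment), not of the test. Under the null the one-way ANOVA's empirical
type-I rate at alpha = 0.05 sits near 0.06 rather than exactly 0.05: the
per-subject rescaling leaves a small rank-one component (the slope error
times the shared prediction profile) in the residuals, a mild sphericity
violation intrinsic to the method — worth remembering when interpreting
p-values near threshold on real data. Power at the reference configuration
exceeds 0.8 for gains well below 0.5 with 500 replicates per gain.

These problem sizes (2000 null replicates, 500 per gain, the 8-subject
reference configuration) are the package's standard experiment sizes; they
give binomial standard errors of about 0.005 on the type-I rate and 0.02 on
power.

## What passing tests do and do not show

The generator produces Gaussian, spatially independent noise, a single
shared task structure with homogeneous subject jitter, and an exactly
linear, exactly known transmission. Real data have spatially correlated
noise, heterogeneous subjects and scanners, imperfect ROIs and an unknown
(certainly imperfect) connectivity model — the analysis on real data
additionally inherits the model's estimation bias, which the paper-style
design addresses by comparing conditions against matched control conditions
rather than against zero. Passing calibration here shows the statistic
behaves correctly under its own assumptions; it does not certify nominal
error rates under real-data violations of them.

## Degenerate inputs and tie-breaks, collected

* ridge at `lambda = 0` requires full column rank; otherwise it errors
  naming the deficiency.
* lasso at `lambda >= max |X'y|` returns exactly zero; zero columns of X
  are left at zero weight.
* cross-validation requires at least 3 rows per fold (Pearson accuracy is
  meaningless below that) and breaks penalty ties toward the larger value.
* `fit_scale` rejects all-zero predictions; slope <= 0 is flagged.
* zero-variance target units are skipped (and counted) in accuracy;
  all-degenerate evaluations error.
* condition order is authoritative from the design; tables are reordered on
  the way into the pipeline, and a missing condition is an error, not a
  silent drop.

## Reproducibility

Every experiment is a pure function of its `simulation_config` (including
the seed); rerunning any pipeline stage with identical inputs produces
byte-identical output files. The numbered scripts under `analysis/` run the
full study — simulate, train, recruit, calibrate, power — writing their
tables under `results/`, and `scripts/acceptance.R` recomputes the headline
quantities from scratch for any seed.
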