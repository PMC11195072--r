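---
title: "Comparing feature-space representations of multivariate time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing feature-space representations of multivariate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtsrep)
```

## The problem

A labeled multivariate time-series dataset — for instance regional
resting-state BOLD recordings from a case–control neuroimaging cohort —
can be summarized for classification in qualitatively different ways.
`mtsrep` implements five such representations and a statistically
careful harness for comparing them:

* **A_region** — all 25 dynamical features of a single region
  (one N × F model per region): sensitive to *where* dynamics differ.
* **A_feature** — one feature's map across all regions (one N × R model
  per feature): sensitive to *which dynamical property* differs.
* **A_uni_combo** — the full region × feature concatenation (one
  N × R·F model).
* **A_FC** — one statistic of pairwise interactions (SPI) across all
  region pairs (one N × P model per SPI): sensitive to disrupted
  coupling.
* **A_FC_combo** — the coupling matrix concatenated with the full
  univariate block (N × (P + R·F)).

Every representation is a pure projection/concatenation of two tensors:
an N × R × 25 univariate feature tensor and a per-SPI N × P pairwise
tensor, so any coefficient can be traced back to a region, feature, or
region pair.

## The feature banks

The univariate bank holds 25 interpretable statistics per region:
autocorrelation timescales (first 1/e crossing, first ACF minimum,
periodicity, whitening-induced change), spectral summaries (centroid
frequency, power in the lowest 20% of frequencies, fALFF in the
absolute 0.01–0.08 Hz band), fluctuation scaling (detrended fluctuation
and rescaled-range exponents), symbolic/information measures (linear
automutual-information timescale, lag-2 histogram automutual
information, tercile pair entropy, transition-matrix column variance),
distributional summaries (raw mean and SD, histogram modes, outlier
timing, high-increment proportion), and shape/residual measures
(3-point rolling-forecast error, longest decreasing / above-mean
stretches, time-reversal asymmetry, exponential fit of embedding
distances). Mean and SD are computed on the raw series; everything else
on the z-scored series, making those 23 features invariant to positive
affine rescaling of the input — a property the test suite asserts.

Two numerical choices deserve explanation:

* Spectral estimates use Welch's method (Hann window, segments of
  `min(T, 64)` samples, 50% overlap, one-sided), shared between the
  univariate features and the spectral SPIs so both see the same
  estimator. The frequency axis is in Hz via the sampling interval, as
  fALFF's band is absolute.
* The rescaled-range exponent uses the Anis–Lloyd finite-sample
  correction: the raw R/S statistic at the short windows used here
  (log-spaced scales in [5, T/4], fit over the lower half) is biased
  upward for uncorrelated data, so the exponent is estimated as 0.5
  plus the slope of log(R/S observed ÷ R/S expected under iid). This
  recovers 0.5 for white noise at the scales the package actually uses.
  Plain order-1 DFA over the same scales is close enough to its
  asymptotic limits (0.5 noise / 1.5 random walk) to be left uncorrected.

The pairwise bank holds 14 SPIs, each declared directed or undirected
once: Pearson correlation, dynamic time warping and its
barycenter-average summary (maximum of the DBA series, 10 iterations
from the elementwise mean), coherence magnitude, phase-slope index in
frequency and time–frequency form (the latter averaged over 4 equal
windows), phase lag index, power-envelope correlation, Gaussian
transfer entropy / directed information / integrated information
(Φ*), additive-noise-model residual dependence, parametric spectral
Granger causality (VAR order by BIC up to 10, Geweke's formula averaged
over a uniform frequency grid), and an augmented Dickey–Fuller
cointegration statistic on the OLS residuals. Directed SPIs populate
all R(R−1) ordered pairs; undirected SPIs only the R(R−1)/2 upper
triangle. All SPIs are computed on z-scored series, so Pearson
correlation coincides with empirical covariance.

The information-theoretic SPIs deliberately use linear-Gaussian
estimators with history length 1: they admit closed forms (transfer
entropy equals half the Granger log variance ratio — asserted to 1e-10
against an independent regression route), are fast enough for dense
pair grids, and are well matched to near-linear signals such as BOLD.
Φ* is computed from the Gaussian mismatched-decoding form with the
natural bipartition {x},{y}, maximizing the decoding information over
the inverse temperature β with a 1-d optimizer; it is symmetric and
non-negative by construction. The spectral Granger statistic is
parametric although nonparametric variants exist; the parametric route
was chosen because it admits an exact integral identity against the
time-domain statistic, which the tests exercise.

## Quality control

Participants whose every region is constant zero (max |x| < 1e-12, a
failed-preprocessing signature) are removed first, then participants
with mean framewise displacement above 0.55 mm. FD follows the Power
convention — sum of absolute frame-to-frame changes of three
translations plus three rotations converted to arc length on a 50 mm
sphere; the radius is a package default since the convention's common
citation leaves it implicit. Rotations are assumed to be in radians.
Participants with neither a recorded mean FD nor motion traces are
retained with a warning rather than dropped.

## The classification harness

Each model is a linear SVM (hinge loss, squared-norm penalty, C = 1)
with inverse-probability class weights, evaluated by balanced accuracy
(mean of sensitivity and specificity; 0.5 is chance at any imbalance)
under stratified 10-fold CV repeated 10 times. All models compared
under one seed share identical fold assignments, which is what makes
paired fold-wise model comparison meaningful.

Within each training fold, columns are imputed by the training median
(per-cell feature failures are recorded as missing rather than zero,
and imputation is a fold-local fitted component like any other) and
normalized by the scaled outlier-robust sigmoid
`1/(1 + exp(-(x - median)/(IQR/1.349)))`, linearly rescaled so training
values span [0, 1]. The 1.349 constant makes IQR/1.349 a consistent
estimate of the SD under normality. The fitted transform is applied
unchanged to the test fold; test values are *not* clipped, preserving
monotonicity in the tails. A zero training IQR falls back to a mean/SD
sigmoid, and a constant training column maps everything to 0.5.

One boundary convention matters under label permutation: a permuted
test fold can contain a single class, where balanced accuracy is
undefined. The fold evaluator then scores the recall of the present
class (the convention of standard ML toolkits); the exported
`balanced_accuracy()` keeps the strict two-class contract.

## Inference

Statistical calibration uses a permutation null: the full repeated-CV
run is repeated under label shuffling (1000 shuffles at production
scale; tests use fewer), and a Gaussian is fitted to the null mean
balanced accuracies. One-tailed p-values come from the fitted tail —
this is what makes very small p-values measurable without millions of
permutations — and Benjamini–Hochberg correction is applied within each
representation family. The observed fold splits are reused across
permutations; because imputation and normalization never see labels,
the per-fold design matrices are computed once and shared, which is
both a large speedup and a leakage-free design (asserted by tests).

Paired model comparisons use the corrected resampled t-test for
repeated k-fold CV: `t = mean(d)/sqrt((1/(kr) + n2/n1) var(d))` with
`n2/n1` the realized mean test/train size ratio and `df = kr - 1` (the
reference treatments delegate the df choice to implementations; kr − 1
is used here and the naive paired t is recovered exactly as n2 → 0).

Fold-wise model selection mimics honest data-driven model choice: per
fold, the unit with the best in-sample training balanced accuracy is
selected and its out-of-sample accuracy retained; ties within 1e-12 are
averaged. For the very wide coupling models, resubstitution accuracy
saturates at 100%, so SPIs are instead ranked per fold in the space of
the first 10 principal components (PCA fitted on normalized training
rows only — the leakage-free reading of the procedure, applied even
though a global fit would have been defensible), and the winner is
refit on its full feature space. `pca_reduce()` provides the analogous
25-component reduction used to probe overfitting of the combined
univariate model; inputs are sigmoid-normalized before decomposition
for consistency with the classifier's view of the data.

## The synthetic generator

`generate_dataset()` draws each participant from a stable VAR(1)
process `x_t = A x_{t-1} + eps_t` with diagonal noise, discarding a
200-sample burn-in. Defaults mirror a typical single-disorder
resting-state cohort: 48 cases vs 116 controls, T = 150 samples at
TR = 2 s, 82 regions, a weakly autocorrelated uncoupled backbone
(diagonal 0.3, unit noise), ages drawn from N(35, 10) truncated to
[18, 65], balanced sexes and two sites. Group effects are planted as
parameter deltas on per-region autoregression, noise scale, mean
offset, or symmetric pairwise coupling; the stationary covariance of
any configuration is available in closed form through the discrete
Lyapunov equation, which is what the recovery tests compare against.
Optional 6-parameter random-walk motion traces exercise the FD/QC path.

What the generator deliberately does not emulate: hemodynamic
convolution, scanner drift and physiological noise spectra, spatial
parcellation geometry, site batch effects, or nonlinear/nonstationary
dynamics. Passing recovery tests therefore demonstrates that the
pipeline detects the kinds of linear-Gaussian group differences it
plants — not that any particular clinical contrast is detectable in
real recordings.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run at desk scale, chosen
as the smallest sizes at which the statistical behavior under test is
unambiguous: null-calibration checks use N = 60 balanced participants,
R = 8 effect-free regions, T = 150 and 200 label shuffles;
planted-effect recovery uses N = 100 with large deltas (autoregression
0.2 → 0.7, doubled noise SD, coupling 0 → 0.35) and reduced permutation
counts (60–100) whose resolution is ample for effects of that size.
Production analyses would raise `n_perm` to the 1000 default.

## Known limitations

* Exact numerical parity with the reference univariate/pairwise feature
  libraries is not a goal; definitions are fixed by this package's
  documentation and validated against closed forms and independent
  oracles instead.
* The information-theoretic SPIs are linear-Gaussian; strongly
  nonlinear coupling will be summarized only through the ANM and DTW
  statistics.
* The directed-information variant here is transfer entropy plus the
  instantaneous Gaussian mutual information of the joint-past
  innovations; glosses of directed information without time lags vary
  across the literature.
* `load_dataset()` reads wide CSV only; a binary array container is out
  of scope for this implementation.
* p-values from the Gaussian tail are as good as the normality of the
  null, which holds well for mean accuracies over 100 folds but should
  be rechecked (the raw samples are retained) for very small or very
  imbalanced cohorts.
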