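---
title: "Category-level odor MVPA: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-level odor MVPA: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odorMVPA)
```

This vignette is the package's account of its science: the generative
model behind the synthetic cohorts, the estimation and analysis models,
the tunable parameters with their defaults and rationale, the numerical
choices, and what the passing test suite does and does not establish
about real data.

## The generative model

### Study design

A session is `n_runs` = 6 runs of `trials_per_run` = 28 trials at a
fixed stimulus-onset asynchrony of 13 s (1.5-s odor pulses, TR 2.3 s,
8-minute runs). Six odors form three perceptual categories with two
exemplars each (citrus C1/C2, mint M1/M2, wood W1/W2). Odor order is a
uniform random permutation constrained so each run holds 4 or 5 trials
of every odor and each odor totals 28 presentations per session; an
optional switch additionally forbids immediate same-odor repeats (off by
default — no stronger constraint is assumed, and the resulting category
repetition rate is the plain permutation expectation, about 31% of
transitions). Four trials per run (14%) are catch trials, spaced every
4–8 trials, on which the subject names the odor's category; catch trials
are modelled as a nuisance regressor and excluded from all pattern
analyses, but they still count as the *preceding* trial when the
following trial's repetition condition is assigned, because they are
real odor presentations.

### Pattern geometry

Voxel patterns are sums of independent Gaussian variance components,
drawn per subject and session:

$$\beta(\text{odor}) = s + \sigma_\text{cat}\,u(\text{cat}) +
  \sigma_\text{odor}\,v(\text{odor}), \qquad
  \text{pattern(odor, run)} = \beta(\text{odor}) + \sigma_\text{run}\,
  \varepsilon$$

with every component i.i.d. standard normal per voxel, scaled as
indicated. Because the components are centred, the expected Pearson
correlation between two cross-run patterns is shared variance over total
variance; with the default $\sigma_\text{cat} = \sigma_\text{odor} =
\sigma_\text{run} = 1$ (and $s \equiv 0$) the expected same-odor /
within-category / across-category correlations are 2/3, 1/3 and 0, i.e.
correlation distances 1/3, 2/3 and 1. Every distance-level result in the
package is checked against this closed form
(`expectedPatternCorrelations()`).

Drug effects are planted as multiplicative rescalings of
$\sigma_\text{odor}$ and/or $\sigma_\text{cat}$ in one group × session
cell. The package default, `plantedDrugEffects()`, multiplies
$\sigma_\text{odor}$ by 1.3 in the placebo group's post session:
within-category pattern separation emerges over time in the control
group and is absent under the drug. The value 1.3 was fixed once at
design time as a moderate-to-large effect — it raises the expected
adjusted within-category distance from 1/3 to about 0.46 — and gives the
three-way interaction a detection power of roughly 0.94 at group sizes
18/14 with 200 voxels (measured by `scripts/acceptance.R`), with type-I
error at the nominal 0.05 under the null generator.

The default ROI size is 100 voxels per hemisphere (200 bilateral),
configurable; real anatomical ROI sizes vary widely and the closed-form
checks hold in the large-voxel limit, so the tolerance of the recovery
tests (±0.02 to ±0.03) reflects 200-voxel sampling error.

### Respiration and BOLD

Cued inhalations are single-peaked flow excursions at each trial onset
on a sinusoidal resting-breathing baseline (0.12 a.u. at 0.25 Hz). The
default waveform is a gamma-shaped flow curve (shape 3) — smooth,
single-peaked, integrable — with peak flow 1.0 ± 0.15 a.u. and duration
1.8 ± 0.25 s at 25 Hz sampling; a triangular waveform is provided
because its peak/duration/volume are exact by elementary geometry,
making it the natural fixture for the feature-extraction tests.
Per-odor volume offsets can be planted to emulate odor-dependent
inhalation (the confound that motivates the sniff nuisance regressor);
they default to zero.

BOLD series are the forward model of the GLM: stick trains convolved
with the canonical HRF and weighted by the run-level patterns, plus a
sniff-coupled term (inhalation-volume train ⋆ HRF, gain 0.5), random
slow cosine drift (amplitude 0.5) and AR(1) noise (ρ = 0.3, innovation
sd 1). Catch trials evoke the voxel-wise *mean* odor response, so the
GLM's single catch nuisance regressor represents them exactly and
noiseless recovery is well-posed. No head motion or spatial structure is
simulated; motion regressors, when supplied, are treated as generic
smooth nuisance series.

## Estimation

### GLM

The design matrix holds, per run: six condition regressors (onset sticks
⋆ canonical double-gamma HRF: peak delay 6 s, undershoot delay 16 s,
unit dispersions, undershoot ratio 1/6, 32-s kernel, 0.1-s microtime
grid), one catch regressor, optional motion columns, one
inhalation-volume regressor orthogonalised against the span of the six
condition columns (so shared variance is credited to the conditions, the
usual convention for parametric nuisance modulators), discrete-cosine
drift terms and an intercept. High-pass filtering is implemented as
cosine nuisance regressors *inside* the GLM rather than by
pre-filtering — the same projection, simpler bookkeeping. Drift columns
are the DCT components with frequency $k/(2NT_R)$ below 1/128 Hz; a run
only loses all drift columns when its duration falls below half the
cutoff period, which is the standard convention for this basis.

Estimation is two-pass: OLS, then AR(1) prewhitening with a pooled ρ̂,
then refit. The naive pooled lag-1 autocorrelation of OLS residuals is
biased toward zero because the residual projection (the drift columns
especially) absorbs slow noise; the package therefore inverts the
mapping ρ → E[residual lag-1 autocorrelation | design] by root finding
on the implied statistic $\mathrm{subdiag}(M\Sigma(\rho)M) /
\mathrm{tr}(M\Sigma(\rho)M)$, with $M$ the residual projector. This
recovers ρ = 0.3 to within ±0.02 on the default design, where the naive
statistic reads ≈ 0.21.

### Sniff features

Respiration traces are smoothed with a 250-ms moving average (the
smoothing scale is a package choice; only "smoothed" is conventionally
specified) and z-scored per run. The cued inhalation is parsed as the
first flow-positive excursion starting within 1 s of the cue, ending at
the first zero crossing; features are its peak flow, duration and
trapezoidal volume. A repeated-measures ANOVA across odors
(`sniffConfoundCheck()`) screens each feature; a feature that differs by
odor belongs in the GLM as a nuisance regressor.

### Patterns

β patterns are z-scored per hemisphere sub-vector and concatenated — the
published normalisation that removes mean signal and lateralisation.
The operation is idempotent and shift-invariant (tested). Single-trial
patterns for the order-control analyses average the cosine-detrended
(0.01 Hz cutoff, same projection machinery as the GLM drift — one tested
code path) voxel signal over scans 2–4 after onset (4.6–9.2 s at TR
2.3 s, approximating HRF peak coverage); the window is a package choice
and configurable.

## Analysis

**Decoding.** Linear SVM, cost 1 (the LIBSVM default), no internal
rescaling (hemisphere normalisation is already applied upstream), no
hyperparameter search. All 12 cross-category train/test assignments are
averaged — a single assignment is an arbitrary choice; averaging removes
it. Ties at zero margin resolve by the classifier's deterministic sign
convention. Folds whose training patterns are all identical are skipped
and logged; if every fold is degenerate the subject is scored at chance.

**Distances.** d = 1 − Pearson r, cross-run pairs only, within session
(pre and post are summarised separately and compared through the session
factor — the baseline-subtraction logic controls within- and
between-session nuisance variation). Adjusted (baseline-subtracted)
distances may be negative and are deliberately not clipped; they are
relative quantities. The per-run categorisation-strength index assigns
each cross-run pair to both runs it involves, so runs are used
symmetrically and the run average reproduces the session-level contrast
exactly.

**Brain–behaviour correlation.** Default Spearman (robust to monotone
nonlinearity in change scores), Pearson available; one-tailed in the
hypothesised direction.

**Group statistics.** The mixed ANOVA is the classical univariate
between/within factorial, computed by projecting the subject × cell
matrix onto orthonormal within-effect contrasts: between effects are
tested against subject-within-group error, each within effect (and its
group interaction) against its factor × subject stratum. Unequal group
sizes use Type III (unweighted-means) hypothesis sums of squares, the
conventional reporting choice. Greenhouse–Geisser ε comes from the
pooled covariance of the contrast scores; ε ≡ 1 for two-level factors,
and Huynh–Feldt is not implemented (GG is the conservative standard).
The implementation is verified to 1e-8 against an independent
multivariate-model route (car) and a hand-computed balanced case; no
linear mixed-effects (random-slope) model is involved — "mixed" here
means between + within factors.

## Numerical choices and degenerate inputs

* Zero-variance pattern vectors make correlation undefined: the distance
  stage fails naming the offending odor/run rather than propagating NaN.
* Zero-variance accuracy vectors (a saturated decoder) make the group t
  test undefined; the test errors, and the pipeline reports the mean
  accuracy with a note instead.
* All-equal ANOVA cells yield F = 0 (not 0/0).
* Clustering ties are broken deterministically by label order via the
  dissimilarity ordering; similarity converts to dissimilarity as
  (scale max − similarity), and the linkage default is average
  (single/complete available) — neither transform nor linkage is
  conventionally fixed, so both are configurable.
* Seeds: every generator takes an explicit seed and restores the
  caller's RNG state; cohort-level seeds derive deterministically from
  the global seed, so identical (config, seed) gives a bit-identical
  cohort and byte-identical result tables.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate at the study's
conditions where that is cheap (group sizes 18/14, 6 runs × 28 trials,
200 voxels) and at reduced replicate counts where only Monte-Carlo error
changes: distance recovery uses 500 simulated subjects (±0.02), decoding
calibration 500 seeds, interaction power and type-I error 500
simulations each, design feasibility 300 seeds, and the smaller unit
tests 60–400 replicates with tolerances matched to their standard
errors. Full BOLD-level runs (forward model → GLM → patterns) are
exercised end to end on single subjects and small cohorts.

## What passing tests do and do not show

The generator reproduces the *structure* of the experiment — design
counts, balanced pseudorandomisation, sniff-coupled nuisance, planted
correlation geometry, session × group effects — but it idealises real
fMRI in ways that matter for interpretation. All subjects share the same
expected geometry (no between-subject heterogeneity in effect size), so
group-level F and t statistics on synthetic cohorts are optimistic
relative to real cohorts; voxel noise is Gaussian, homoscedastic and
spatially unstructured; there is no head motion, physiological
artefact beyond the modelled sniff coupling, or spatial correlation; and
behavioural ratings are Gaussian around planted means rather than
subject-idiosyncratic. Passing tests therefore establish correctness of
the estimators and calibration of the inference under the stated model,
not effect sizes or power for any particular real dataset. The analyses
are ROI-based only (no searchlight), distances are raw Pearson (no
cross-validated Mahalanobis variants), and decoding is the pairwise
cross-category scheme — multiclass and cross-session decoding are out of
scope.
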