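---
title: "Methods: dynamic connectivity states, temporal features and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic connectivity states, temporal features and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
model behind each stage, the tunable parameters and why their defaults
are what they are, what the synthetic cohort generator does and does not
emulate, and the numerical decisions that were genuinely open.

## The model

A scan is a matrix of `T` time points by `C` component time courses
(intrinsic connectivity networks extracted upstream by a group-ICA
pipeline; the package starts *after* that step). The working assumption
of the state analysis is that the instantaneous cross-component
covariance is not constant but switches among a small number `K` of
recurring patterns ("brain states"), and that the switching process is
well approximated by a first-order Markov chain at the time scale of the
sliding window. Under that model:

* a tapered sliding window localises the Pearson correlation in time,
  giving a sequence of `C x C` windowed connectomes per scan;
* k-means under the correlation distance `1 - corr` pools all windows
  and recovers the state patterns as centroids, and each window receives
  a state label;
* the per-scan label sequence is summarised by the maximum-likelihood
  transition matrix `a[i, j] = p(s(t+1) = i | s(t) = j)` (column
  stochastic) and the occupancy rate (fraction of windows per state);
* dynamics-aware features (state-specific mean FNC, occupancy,
  transitions) are related to a clinical severity score (CDR-SOB) by
  partial correlation adjusted for age and gender, with
  Benjamini-Hochberg control applied within each feature family, whose
  sizes at the defaults are 1378 (per-state FNC, `C = 53`), 3 (OCR) and
  9 (transitions);
* conversion from the healthy to the impaired group is predicted from
  baseline features with a polynomial-kernel SVM after ADASYN
  oversampling of the minority class.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window_trs` | 20 | TRs (44 s at TR 2.2 s) | inside the 30-60 s range where windowed correlation tracks connectivity fluctuations without drowning them in estimation noise |
| `gaussian_sigma` | 3 | TRs | tapers the rectangle so window edges enter smoothly; `sigma -> 0` recovers the plain rectangle |
| `step` | 1 | TRs | maximal temporal resolution; windows start at 0..T-W-1, so a 159-point scan gives 139 windows |
| `k` | 3 | states | the motivating cohort's elbow choice; `elbow_select_k()` re-estimates it on new data |
| `n_replicates` | 20 | restarts | k-means++ restarts; the best fit by inertia is kept |
| `max_iter` | 1000 | iterations | per-run cap, conservative reading of "1000 iterations" (restarts are controlled separately) |
| `cutoff_hz` | 0.15 | Hz | keeps the band where resting-state covariation lives; must stay below Nyquist `1/(2 TR)` |
| `detrend_order` | 3 | - | removes linear, quadratic and cubic drifts |
| `z_threshold` | 4 | robust SD | despiking threshold on deviations from an 11-point running median |
| `alpha` | 0.05 | - | significance level on BH-adjusted p values |
| `beta` | 1 | - | ADASYN balance level: 85/40 classes yield exactly 45 synthetic samples |
| `degree_grid`, `cost_grid` | {2, 3}, 10^(-1..1) | - | SVM hyperparameter grid searched by inner 5-fold CV; the source analysis reports only that hyperparameters were optimised, so the grid is a documented package choice |

## The synthetic cohort generator

`generate_cohort()` defines the study conditions the tests run under.
Each subject carries a latent state sequence from a sticky Markov chain
(regime steps of 10 time points; stickiness 0.85, i.e. mean dwells on
the order of a minute, in line with reported dFNC dwell times), and each
regime step contributes zero-mean Gaussian samples with that state's
covariance plus white observation noise (sd 0.2). The three default
state covariances share strong within-coupling in the sensory blocks
(auditory/sensorimotor/visual) and differ mainly in the
sensorimotor-visual coupling, which ramps from negative (state 1) to
strongly positive (state 3, which also decouples the sensory blocks from
the rest) -- the qualitative structure reported for the three states in
the motivating cohort. Scan length defaults to 159 time points (164
volumes minus 5 dummy scans), so each scan contributes 139 windows.

Group structure: occupancy profiles default to roughly (0.22, 0.52,
0.26) for healthy and (0.30, 0.52, 0.18) for impaired subjects --
state 2 is the dominant "baseline" state for everyone, the impaired
group spends more time in state 1 and less in state 3. Because the
literature this emulates reports the direction of those group
differences inconsistently in different places, the direction is a
*parameter* (swap or edit the occupancy profiles), not a constant.
CDR-SOB is 0 for every healthy subject and
`2.68 + 12 * (occupancy_1 - expected) + N(0, 1.5)` truncated to
[0.5, 9] for impaired subjects; ages are N(69.8, 8.6) / N(75.1, 7.9)
and gender Bernoulli(0.40) / Bernoulli(0.60) for the two groups,
matching the demographic moments of the motivating cohort. All
randomness comes from R's global RNG: `set.seed()` before a call makes
cohorts bitwise reproducible.

What the generator does *not* emulate: haemodynamics, scanner noise
spectra and autocorrelation, head motion, voxel-level structure,
repeated scans per subject, and within-state nonstationarity. Passing
recovery tests therefore shows the pipeline is correct under its own
model assumptions -- not that real data satisfy those assumptions.

## Numerical choices

* **Correlation-distance k-means.** Vectors are centred and scaled to
  unit norm, after which `1 - corr(a, b) = ||a - b||^2 / 2` exactly, so
  plain Euclidean k-means implements the correlation distance; the
  identity is asserted to 1e-12 in the tests. Restarts are k-means++
  seeded; rare empty-cluster failures re-draw the seeds.
* **Elbow rule.** The within/between distance ratio falls until the true
  structure is reached and then flattens or turns back up (splitting a
  cluster collapses the between-centroid distance). A maximal-curvature
  rule on this curve proved unstable -- near-ties decided by restart
  noise -- so the package selects the *smallest* `k` whose ratio lies
  within 5% of the curve range of the global minimum (a parsimony
  tie-break in the spirit of the one-standard-error rule), and flags
  shallow curves or boundary minima as low-confidence.
* **Window-count convention.** Windows start at 0, 1, ... while
  `start + W <= T - 1`: count `T - W` at step 1, reproducing the
  139-window dimension of a 159-point scan.
* **Tapered correlation.** The taper acts as observation weights inside
  a weighted Pearson correlation (not as a premultiplication of the
  data); with uniform weights it equals the plain Pearson correlation to
  machine precision, which is the tested anchor.
* **Low-pass filter.** The family is not dictated by the analysis, so a
  5th-order Butterworth applied forward-backward (zero phase, preserving
  window timing) is used, with odd-reflection padding because a bare
  forward-backward pass has start-up transients that would corrupt the
  scan edges.
* **Despiking.** Deviations from an 11-point running median beyond 4
  robust standard deviations (1.4826 x MAD) are replaced by the running
  median. A zero MAD (constant column) falls back to replacing any
  deviating point. The procedure is order-preserving and idempotent.
* **Positive-definite repair.** Block templates for state covariances
  are repaired by eigenvalue clipping at 1e-3 followed by
  re-normalisation to unit diagonal; states whose repaired versions
  correlate above 0.9 trigger a distinguishability warning.
* **Empty transition columns.** A state never departed from yields an
  undefined column; the default fills it uniformly (1/k) and flags it,
  keeping feature tables rectangular for classification; a "missing"
  mode is available for association analyses.
* **Degenerate partial correlations.** An input fully explained by the
  covariates has zero residual variance; the result is reported as
  `r = 0` with a missing p value and a degeneracy flag rather than as a
  spurious correlation.
* **Classifier evaluation.** Per repeat, ADASYN synthesises minority
  samples, a majority subset of equal size forms the balanced training
  set, hyperparameters are chosen by inner 5-fold CV on the training set
  only, and evaluation uses held-out real samples. One design point was
  genuinely open: if *all* real minority points seed the synthetic
  interpolants and are then evaluated, minority geometry leaks into
  training -- the package measures chance-level behaviour honestly only
  when a fraction of the minority (default 20%) is held out of ADASYN
  seeding and reserved for evaluation, so that is the default
  (`minority_holdout = 0` reproduces the literal all-minority protocol
  for comparison). Decision scores are standardised with training-set
  statistics before the dot-product kernel, and AUC is the rank
  (Mann-Whitney) statistic, invariant to monotone score transforms.
* **Positive class.** Accuracy/sensitivity/specificity take the
  non-converting (majority) group as the positive reference, stated in
  every report; a `positive` argument flips it.
* **Scans as rows.** Repeated scans per subject are treated as
  independent rows, as in the motivating analysis; mixed-effects
  handling is out of scope and flagged as a limitation.

## Problem sizes used by the test suite

The recovery suite clusters a 60-scan cohort (30 healthy, 30 impaired;
53 components, 139 windows each, 8340 windows total), checks centroid
recovery against the planted covariances (correlation >= 0.95 after
optimal matching), elbow selection of `k = 3`, group-wise clustering
consistency (matched centroid correlation >= 0.95), and
transition/occupancy recovery on 20,000-step validation chains (max
transition error <= 0.05; occupancy within 0.02 of the stationary
distribution in cross-scan mean). Statistical validity uses 200 null
cohorts (raw p < 0.05 rate within 0.05 +/- 0.02 per family; BH
false-discovery proportion near alpha) and 100 planted-effect cohorts
(>= 90 recoveries of the linked occupancy feature with correct sign at
adjusted p < 0.05). Classifier sanity averages shuffled-label AUC over
shuffles (chance within 0.5 +/- 0.1) and requires >= 95% accuracy on
well-separated classes. These sizes are the package's validation
choices; larger cohorts only sharpen the same checks.

## Known limitations

* The Markov assumption is imposed at the regime-step scale; windows
  spanning a regime boundary are mixtures, so window-label accuracy is
  bounded away from 1 even with perfect clustering.
* The correlation-distance k-means ignores within-state covariance of
  the connectome estimates; no graphical-lasso regularisation of the
  windowed covariance is applied.
* Association treats scans as exchangeable rows; subject-level clustering
  of repeated scans is not modelled.
* The elbow criterion, like all internal validity indices, can be
  indecisive on weakly structured data; the low-confidence flag should
  be honoured rather than overridden.
* Real fMRI violates the generator's assumptions in known ways
  (autocorrelation, motion artefacts, non-Gaussian noise); recovery
  results bound implementation correctness, not field performance.
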