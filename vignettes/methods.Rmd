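---
title: "Multiverse analysis of task-fMRI amygdala-mPFC development: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiverse analysis of task-fMRI amygdala-mPFC development: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Developmental task-fMRI findings — here, age-related change in amygdala
reactivity to emotional faces and in amygdala–mPFC functional connectivity
across ages 4–22 — are notoriously sensitive to analysis choices. This
package implements the full analysis machinery for asking *how* sensitive:
every scan-level estimator (condition-contrast GLMs, single-trial LSS betas,
gPPI and beta-series connectivity), the multilevel longitudinal models that
turn scan-level estimates into age trajectories, a specification-grid engine
that runs every combination of analysis decisions and summarizes the
resulting curve, and variance-decomposition ICCs for test–retest
reliability. Because the original cohort's imaging data are not public, the
package is organized around a synthetic-data generator with known
parameters, so that every stage has a parameter-recovery oracle: if the code
is right, it must recover what was planted.

# The synthetic study

`simulate_study()` emulates the design of the motivating study:

* **Cohort.** An accelerated longitudinal sample: 40 participants with one
  scan, 31 with two, 27 with three (98 participants, 183 scans), starting
  ages uniform on 4–22 y, 1.5 y between waves (ages capped at 22), a scanner
  change at wave 3, and counterbalanced block order.
* **Task.** 48 face events per run (24 fear, 24 neutral), 350 ms each,
  jittered ITIs in 3–10 s, 130 volumes at TR 2 s. ITIs are drawn uniformly
  and, when the draw overflows the 260-s run, shrunk linearly toward the 3-s
  floor; the resulting median ITI is ~5 s. The original study optimized its
  stimulus order with a genetic algorithm; design-efficiency optimization is
  not the object of study here, so simple seeded jitter is used.
* **BOLD generation.** Per-trial neural amplitudes follow
  `baseline_c + age_slope_c (age − 12) + habituation(trial, age) + stable
  participant shift + trial noise`, with the seed and target trial noise
  correlated at `coupling_rho_c` within condition `c`. Amplitude-weighted
  event impulses (0.1 s grid) are convolved with a peak-normalized
  double-gamma HRF and bin-averaged to the volume grid, then AR(1) noise,
  polynomial drift, a shared low-frequency global component, and FD-coupled
  motion artifacts are added. Head motion is a 6-parameter random walk with
  occasional spikes whose expected mean FD decreases with age
  (`motion_age_slope`), mirroring the higher motion of younger children.
* **ROI panel.** Eight amygdala variants (native bilateral/left/right,
  high/low-signal, and atlas-space re-extractions emulating the
  native-vs-MNI and segmentation forks as correlated columns), three mPFC
  spheres and a large vmPFC mask, a global-signal column, and WM/CSF tissue
  columns. No images are synthesized; image-level preprocessing is out of
  scope and its forks are represented as labeled generative or pipeline
  variants.
* **Anxiety.** Raw parent-report separation-anxiety scores decrease with age
  (~0.35 points/yr); standardized t-scores are age-invariant by
  construction. Item-level responses allow a configurable missingness
  fraction for the 5-NN imputation step. Adults (18+ at first scan) have no
  parent reports, so association models run on the child subsample.

Default generative values live in
`inst/extdata/default_generative_params.yaml` and are chosen once to
reproduce the qualitative regime of interest: a detectable negative
fear-reactivity age slope (−0.05 units/yr against scan-level noise that
yields cohort-level *t* ≈ 3), condition-dependent coupling (fear 0.35,
neutral 0.15) with no age trend in connectivity, habituation that weakens
with age, and motion decreasing with age. What passing tests show is that
the estimators recover *these* planted effects at *this* study size; they do
not show that real amygdala development behaves this way, and the generator
deliberately omits real-data features such as spatial structure,
physiological noise, task-correlated motion, and non-Gaussian artifacts.

The stable participant amplitude shift is derived deterministically from the
participant id, so a participant keeps their shift across waves without any
global random-number state; this is what gives scan-level measures a
non-trivial test–retest ICC.

# Scan-level estimation

**GLM.** `build_design_matrix()` assembles convolved task regressors
(double- or single-gamma HRF), their backward-difference temporal
derivatives, a drift basis, and a motion nuisance set (6, 24 = parameters +
derivatives + squares, or 18 + WM + CSF). Volumes with FD > 0.9 mm get
weight 0 (the threshold is strict; 0.9 itself survives) and scans with more
than 40 suprathreshold volumes are flagged excluded. `fit_glm()` solves
weighted least squares with 0/1 weights implemented as row deletion —
verified equivalent — and optionally prewhitens with a single-lag
Cochrane–Orcutt step: the lag-1 residual autocorrelation is estimated on
acquisition-time-adjacent uncensored pairs only, and quasi-differencing
respects censoring gaps the same way. This is a deterministic, testable
substitute for voxelwise FILM-style prewhitening. The high-pass option is a
discrete-cosine basis with `floor(2 · T · 0.01 Hz)` components entered as
regressors — a deterministic substitute for running-line filters; only the
fork's label needs to match. "Preprocessing software" and "GLM software"
forks are emulated honestly as labeled variants (the C-PAC branch reads the
atlas-variant ROI columns; the AFNI branch fits OLS instead of AR(1)).

**LSS.** One GLM per trial (48 per scan): the target trial's regressor, one
collapsed regressor for the other 47, the nuisance set, drift basis and
censor weights. A trial whose regressor support is fully censored returns a
flagged missing beta, which is propagated, never imputed. The LSS = LSA
equivalence at non-overlapping spacing is exact when the collapsed regressor
is correctly specified (trial-constant amplitudes); with heterogeneous
amplitudes the misfit leaks through the shared drift basis and the
equivalence is approximate — both facts are tested.

**Global-signal centering.** Post hoc distribution centering subtracts, per
trial, the mean beta across a configurable ROI panel. The original work
centered on a mean whose exact ROI set is unspecified; the panel is exposed
as configuration, and the recovery tests estimate the global component from
a broad auxiliary panel, which is the regime in which centering restores the
generative coupling (centering on a 2-ROI panel is exactly degenerate: it
forces correlation −1).

**gPPI.** One interaction regressor per condition plus psych and physio
terms. Without deconvolution the interaction is the mean-removed seed times
the (optionally centered) convolved task regressor — product-with-convolved
is the adopted construction; the alternative is noted as a hidden fork. With
deconvolution the seed is inverted to the neural scale by ridge regression
against the HRF convolution operator on the volume grid
(`argmin ‖Hn − y‖² + λ‖n‖²`, λ scaled by `mean(diag(H'H))`, default 1),
multiplied by the 350-ms task indicator (fine grid, bin-averaged), and
re-convolved. The reference implementation the original study used is known
to be unstable under small algorithmic tweaks, so exact replication is
neither possible nor intended; λ sensitivity is exposed as an optional
fork, and the main deconvolution pipeline does not center the task regressor
(centering is a separate fork). Collinearity between PPI and psych/physio
columns beyond |r| = 0.99 is flagged in the output.

**BSC.** Pearson correlation across one condition's paired trial betas,
Fisher-z transformed; |r| = 1 is clamped to 1 − 10⁻⁶ and flagged,
zero-variance series return missing with a reason.

# Group-level models

All group models are multilevel regressions with participant random
intercepts and optionally participant-varying age slopes, always adjusted
for mean FD, optionally for block order and scanner. Age enters linearly,
with an added quadratic term, or as 1/age (raw years); age is centered at
12 y and kept in years, so slopes read directly in units/year (a per-decade
rescaling was considered and dropped — lme4 and JAGS are numerically
comfortable with the ±10 range). For specification curves every age form is
mapped to a derived `age_trend` term: the implied per-year slope at the
centering age — the linear coefficient for linear and quadratic forms, and
`−b/144` for the inverse form (the derivative of `b/age` at 12 y, which
also flips the sign since 1/age decreases in age) — so medians and sign
proportions compare like with like across forms.

Two estimation paths:

* **`fast_freq`** — REML via lme4, Wald intervals with Satterthwaite degrees
  of freedom. Random-slope models can carry more random effects (196) than
  scans (183); they remain estimable through shrinkage, so the conservative
  lme4 guard is relaxed and singular fits are flagged via the `converged`
  column rather than erroring. The robust variant iteratively reweights by
  Huber weights on the residuals.
* **`bayes_mcmc`** — Gibbs sampling via JAGS: 4 chains, 1000 warmup + 1000
  sampling iterations, student-t(3, 0, 10 standardized units) priors on
  fixed effects (the scale multiplies `sd(y)/sd(x)` per coefficient),
  half-student-t priors on variance components, posterior median and
  equal-tailed 95% interval. Non-intercept columns are centered internally
  for mixing and the intercept is mapped back. Convergence is judged by
  split-R̂ < 1.01 on the fixed effects; failures are flagged, never silent.
  The robust variant swaps in a student-t likelihood with estimated degrees
  of freedom. Random intercept and slope variances are independent (no
  correlation parameter) — a deliberate simplification of the sampler; the
  frequentist path estimates the full covariance.

A full 2,808-specification Bayesian multiverse is not desk-scale, so the
sweeps default to the frequentist path and the Bayesian path is exercised on
single fits and subsamples; agreement between the two paths on well-behaved
fits is a tested invariant (point estimates within 0.01 units/yr at the
default study size).

The within/between parametrization splits age into the participant's mean
age (between) and the deviation from it (within); a purely cross-sectional
table flags the within term as structurally inestimable. Outlier handling
follows the ±3 SD rule applied to the outcome over all scans before the
model (whether the original rule was per-contrast or per-specification is
unstated; per-measure-over-all-scans is the choice here, and it is logged),
with the "+ robust regression" fork additionally switching the likelihood.
The trial-dynamics family has three variants — scan-level Spearman slopes
regressed on age, half-mean models with an age × half interaction, and
trial-level models with an age × trial interaction and random intercepts for
participants and scans (the original random-effects structure for these
models is unstated; this nesting is documented, not asserted as theirs). For
the anxiety models, outcomes are z-scored so the brain coefficient is
invariant to affine rescaling of the instrument, and 5-NN imputation
completes missing SCARED items: distances are Euclidean on standardized,
mutually observed items, ties break by row order, and fewer than k
candidates triggers a flag rather than failure.

# The multiverse engine

A grid is a list of parts — factorial named lists and/or curated data-frame
blocks — crossed together by `enumerate_specs()`, each specification getting
a stable content-hash fork id. The packaged default grids reproduce every
printed specification count: 2,808 = 156 × 18 for reactivity, 288 = 4 × 4
mPFC × 18 for gPPI, 168 = 3 × 4 × 2 × 7 for BSC, 42 = 3 × 2 × 7 for trial
dynamics, and 18/90/18/12 for the anxiety curves. The printed counts are
published; the memberships are not, so the grid compositions here are this
package's reconstruction: the 156 participant-level reactivity pipelines are
a fully-factorial FSL branch (2 HRFs × 3 nuisance sets × 2 detrend options ×
2 estimate types × 5 native ROIs = 120) plus a C-PAC branch (2 GLM software
variants × 3 nuisance sets × 2 estimate types × 3 atlas ROIs = 36); the 18
group-level models are 8 linear (4 covariate sets × 2 random-slope options)
+ 4 robust linear + 4 quadratic + 2 inverse-age; the 7-model set is 4
covariate sets + quadratic + no-random-slopes + inverse, all robust.

`run_multiverse()` executes specifications sequentially, catching and
logging per-spec failures (a sweep aborts only past 20% failures).
`build_spec_curve()` ranks estimates ascending, takes the median (midpoint
rule for even counts), and reports the proportion of estimates sharing the
median's sign — the "same direction" reference is the median, which the
original text leaves unstated — and the proportions of 95% intervals
excluding zero, overall and in the median's direction. Decision-level rank
summaries (median and IQR of curve ranks per level, decisions ordered by the
spread of their level medians) mirror the standard two-panel curve figure.
`decision_effects()` regresses point estimates on treatment-coded decision
indicators; fully aliased decisions error by name, partial aliasing in
curated grids is flagged. No formal null-hypothesis test of a curve is
computed — evidence is summarized as proportions, deliberately.

# Reliability

`icc_variance_components()` computes test–retest ICCs from the measure's
multilevel model (same mean-FD covariate as the group models; a
covariate-free variant is exposed), keeping every participant including
single-visit ones. The fast path reports `σ²_between / (σ²_between +
σ²_within)` from an REML fit with a seeded participant-level bootstrap
interval (1000 resamples by default). The posterior-predictive path draws,
per posterior sample, one predictive replicate conditioned on the sampled
participant effects and one with participant effects redrawn, and reports
`1 − var(conditional)/var(marginal)` summarized over draws — negative values
are possible and mean the conditional predictive variance exceeded the
marginal one. Conditioning is at observed covariate values (the alternative,
reference-value conditioning, is unstated in the original and not used).
Bands: poor < 0.4 ≤ fair < 0.6 ≤ good < 0.75 ≤ excellent (half-open on the
lower edge).

# Numerical choices and degenerate inputs

* HRF kernels are peak-normalized so betas are in generative amplitude
  units; the double-gamma uses shape-6/shape-16 gamma densities with a 1/6
  undershoot, zero at t = 0, 32-s support.
* Sub-TR (350 ms) events are represented on a 0.1-s grid and bin-averaged
  into TR bins — point-sampling at volume times would mostly miss them.
* FD converts rotations to millimetres on a 50-mm radius (the citation chain
  leaves the radius unstated); the first volume is assigned 0 and `mean_fd`
  is the mean of the full series.
* Spearman slopes: ties mid-ranked; constant series return 0 with a
  degeneracy flag; fewer than 3 usable trials return missing with a reason.
* Fork ids are 12-hex-character SHA-1 content hashes of the decision
  mapping, stable across sessions for resumability.
* Degenerate inputs error loudly and early: empty conditions, infeasible ITI
  budgets, non-6-column motion input, rank-deficient designs (offending
  columns named), constant physio seeds, zero-variance ICC measures.

# Problem sizes

The test suite and the acceptance script scale the studies to sizes chosen
for tight feedback: planted age-slope coverage uses 100 (tests) / 40
(script) independent 183-scan cohorts simulated at the measure level —
the full BOLD stack is covered by its own exact oracle (noiseless per-trial
amplitude recovery within 10⁻⁶) and by end-to-end reduced-grid runs, so
repeating it hundreds of times would add cost, not information. Habituation
× age sign recovery uses 100 cohorts of 65 participants at the
trial-amplitude level; the ICC grid uses 50 replicates per level at 100 × 3;
null calibration pools a 24-specification group-level grid over 15–30
independent zero-effect cohorts — pooling matters, because within one cohort
all specifications share the scan-level noise and per-cohort sign
proportions are degenerate near 0 or 1. The analysis drivers under
`analysis/` run the full published grid sizes (2,808 specifications and the
rest) on one simulated cohort with the frequentist path.

# Known limitations

* The generator produces ROI timeseries, not images; registration,
  smoothing, and segmentation forks exist only as labeled correlated
  variants, so the multiverse spans a narrower (and cleaner) space than a
  real image-level multiverse would.
* The Gibbs-sampled Bayesian path has no divergence diagnostics (an HMC
  concept); split-R̂ and flagged singular fits are the convergence surface.
* Grid memberships beyond the printed counts are reconstructions; decision-
  point effect estimates on curated (non-factorial) grids can be partially
  aliased, which the engine flags but cannot undo.
* The exact ITI distribution and stimulus-order pseudorandomization of the
  original design are unrecoverable; the median ITI is close to, but not
  exactly, the published 4.93 s.
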