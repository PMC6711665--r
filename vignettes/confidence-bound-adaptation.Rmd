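---
title: "Confidence-dependent bound adaptation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-dependent bound adaptation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boundshift)
```

This vignette documents the models, the synthetic-data generator, the
estimation machinery and the numerical choices behind **boundshift**, and
states what the package's tests do and do not establish about real data.

## The decision model

A single trial is a Wiener diffusion with unit within-trial noise between
absorbing bounds at 0 and $a$, starting at $w\,a$ with $w = 0.5$ (unbiased),
drifting at mean rate $v$. Under accuracy coding the upper bound is the
objectively correct response, so $v \ge 0$ indexes evidence quality. Observed
response time is the first-passage time plus a non-decision time $T_{er}$.
Reported magnitudes (e.g. a baseline bound near 2) are only meaningful under
this $\sigma = 1$ convention; a process with noise $\sigma$ is internally
rescaled ($a/\sigma$, $v/\sigma$). The model is deliberately plain — no
inter-trial variability parameters ($s_v$, $s_z$, $s_t$) — matching the model
actually fit in this line of work.

The first-passage density uses the standard pair of series representations
(a sum of Gaussian images for small rescaled time, a sine series for large),
switching to whichever needs fewer terms for the requested absolute error
(default `tol = 1e-7`; the term-count rules bound the truncation error).
Closed forms: $P(\text{correct}) = 1/(1+e^{-av})$ and mean decision time
$(a/2v)\tanh(av/2)$, with the limit $a^2/4$ at $v = 0$.

The simulator is Euler–Maruyama with two accuracy refinements: the crossing
time within the final step is linearly interpolated, and a diffusion-bridge
check catches excursions that cross and return *within* a step, which removes
the leading $O(\sqrt{dt})$ boundary-miss bias of the naive scheme. With the
bridge check, a step of $10^{-3}$ s already gives Kolmogorov–Smirnov
agreement with the analytic distribution near the Monte-Carlo noise floor at
$10^6$ trials; the test suite additionally checks a $10^{-4}$ s run. Paths
that fail to absorb within `max_time` (default 20 s) are flagged censored,
never silently truncated.

## What the synthetic cohort emulates

`generate_cohort()` produces multi-participant trial tables with known ground
truth, emulating a coherence-varying random-dot experiment:

* **Conditions.** Five coherence levels $\{0, .05, .1, .2, .4\}$ mixed
  uniformly; drift is `drift_gain` × coherence (group mean 3.5, giving mean
  accuracy near 0.7 and ceiling accuracy ≈ 0.92 at the highest coherence).
  Participant baselines: bound 2.0 (SD 0.3), non-decision time 0.38 s
  (SD 0.09) — the across-participant values reported for this kind of task.
  330 rated trials per participant in 6 blocks: that is the usable rated
  count behind the published per-category trial numbers (they sum to ≈330,
  not to the 540 presented trials, because one block type yields no 6-point
  rating and practice/time-outs are excluded).
* **Confidence.** After the bound is hit, accumulation continues for 1 s with
  the same drift and noise (the "blank screen" buffer account; the continued-
  motion condition was behaviorally indistinguishable, so only one condition
  is generated). The confidence variable — distance travelled to the chosen
  bound plus the signed post-decisional increment plus rating noise — is cut
  by five thresholds into ratings 1..6. The thresholds and rating noise are
  free calibration knobs, not claims: they were set once so the high / low /
  perceived-error mix is ≈ 192 / 115 / 24 trials per 330 (58/35/7%), and held
  fixed. This yields below-chance accuracy for ratings 1–2 (certainty about
  errors) and monotonically rising accuracy with rating, without targeting
  any specific accuracy value.
* **Sequential coupling.** The next trial's bound is the participant baseline
  plus an increment determined by the previous trial's confidence category
  (defaults +0.08 after low confidence, +0.26 after perceived errors — the
  magnitudes reported for this effect), or alternatively by the previous
  Pe amplitude (linear, for the EEG analyses) or by previous accuracy (a
  discriminating counterexample for the stratified analyses). Carry-over
  crosses block boundaries by default and never participant boundaries;
  `block_reset = TRUE` restarts it each block.
* **Slow drift.** A standardized $1/f^{|\beta|}$ latent state (spectral
  synthesis, $\beta = -1$ by default) multiplies drift via
  $\exp(\text{amplitude}\cdot s_t)$, normalized to mean 1. The same state can
  optionally modulate the bound (`bound_amplitude`, default 0). This second
  channel is a deliberate design choice: if the slow state affects only
  drift, a correctly specified regression absorbs it entirely in the drift
  coefficients and the raw lag-n *bound* effect stays unbiased — we verified
  this empirically — so the confound that the lag-n+2 correction is designed
  to remove never arises. A shared arousal/motivation state that moves
  caution as well as evidence quality is also the more plausible reading of
  slow behavioral drift, and with `bound_amplitude > 0` the raw-versus-
  corrected contrast behaves exactly as the correction presumes.
* **EEG-like amplitudes.** Pe and ERN load linearly on the standardized
  post-decisional *error* evidence (Pe gain 3 µV/SD, noise SD 4; ERN gain
  1.5, noise SD 6.7), giving a Pe–ERN correlation of ≈ 0.18 — the calibration
  target — with the Pe tracking uncertainty much more strongly than the ERN.

What passing tests on this generator show: the estimation pipeline is
unbiased and well calibrated *when the generative model holds*. What they do
not show: that real confidence ratings arise from post-decisional
accumulation, that real slow drift is log-normal $1/f$, or that real EEG
amplitudes are linear in error evidence. The generator is a measurement
instrument for the pipeline, not evidence about brains.

## The hierarchical regression fit

`build_design()` codes, for each usable trial, indicators for the previous
trial's confidence category (lag n) and the category two trials later
(lag n+2), with high confidence fixed to zero as the reference, entering both
the bound and the drift regressions; evidence strength enters the drift
regression as a per-participant standardized covariate. Edge trials with
undefined lags are dropped and counted. Both regressions use an identity
link; a proposal that realizes $a \le 0$ on any trial (or $T_{er}$ above an
observed RT) has zero likelihood and is rejected, which is the positivity
guard.

Estimation is Metropolis-within-Gibbs. Each participant has a parameter
vector (baseline bound, non-decision time, drift intercept, and all
regression coefficients) drawn from group-level normals; group means and
variances get conjugate Gibbs updates (normal and inverse-gamma). The
participant vectors are updated in three random-walk blocks — bound
parameters, drift parameters, non-decision time — whose proposal scales adapt
toward 25% acceptance during burn-in only (Robbins-Monro on the log scale,
with running posterior SDs), then freeze, so the post-burn-in chain is a
fixed Markov kernel. Chains initialize from per-participant EZ-style moment
estimates, jittered per chain. Priors are weakly informative: group baseline
bound positive-truncated normal around 2, non-decision time around 0.3 s,
coefficients normal(0, 2), variances inverse-gamma(2, 0.1) — all
configurable via `prior_control()`.

Because participants are shrunk toward the group, statistical inference is
meaningful at the group level only; participant-level summaries are emitted
(`tidy(fit, level = "participant")`) but should not be compared across
participants. Convergence is checked with the classic Gelman-Rubin R-hat on
the group-level chains (warning outside [0.98, 1.02]); model comparison uses
DIC with the usual effective-parameter correction; and condition differences
are scored by posterior overlap, two-sided by default
(`posterior_p()`; one-sided available — published one-sided values would be
about half ours). Where no draw crosses zero the Monte-Carlo floor $1/N$ is
reported rather than 0.

The desk-scale default is 4 chains × 2000 samples, half burn-in — enough for
stable group-level summaries at the cohort sizes used here (the test suite
checks that reduced-scale and larger runs agree within one posterior SD).
Full-scale inference in this literature uses 10 chains × 10000 with
thinning 2 (`mcmc_control(n_chains = 10, n_samples = 10000, thin = 2)`).

## Removing slow-drift confounds

Confidence two trials ahead cannot causally influence the intervening trial,
but it sits in the same slow-performance state, so its fitted "effect" on
trial n+1 measures the confound alone. `drift_corrected_effect()` therefore
subtracts the lag-n+2 posterior from the lag-n posterior *drawwise within the
joint fit*, preserving their posterior correlation — the corrected interval
would be too wide if the two were estimated separately. Swapping the lag
roles negates the corrected draws exactly, which the tests exploit as an
alignment check. `matched_trial_subset()` implements the complementary
control: target-category trials are compared only against high-confidence
trials whose trial n+2 falls in the target category, equating the slow-state
context by construction rather than by subtraction. `stratified_fit()`
re-runs the pipeline within trials whose *predictor* trial was correct (or an
error), separating graded confidence from objective accuracy; participants
with an empty confidence cell inside the stratum are dropped and counted.

At the descriptive level, `caution_statistic()` mirrors the same logic:
central RT × mean accuracy per previous-confidence category, conditioned on
trial n and on trial n+2, with corrected deltas. The central RT defaults to
the median (the text of the originating methods) with a mean option (their
figure axis), exposing rather than hiding that discrepancy. The scale-free
diagnostic `spectral_slope()` uses the raw periodogram with log-binned
frequencies — the estimator was unspecified in the source, so it is fixed
here and validated by a generator round trip (slopes recovered within ±0.15).

## EEG covariates

Single-trial amplitudes are window means after a zero-phase second-order
Butterworth low-pass at 10 Hz (only the cutoff was specified; the order and
zero-phase realization are this package's documented choice): ERN at FCz,
−10…90 ms; Pe at Pz, 250…350 ms, endpoints snapped to the nearest sample and
inclusive. No baseline correction is applied by default (none was
specified). Robust predictors are per-participant average-tie ranks; the Pe
is residualized on the ERN per participant before quantile binning (five
equal-count bins, remainder to the lower bins, bin 1 = reference), so binned
effects reflect Pe variance not shared with the ERN. Raw-Pe and
residual-Pe binning coincide exactly when the in-sample Pe–ERN correlation
is zero, and differ otherwise — both variants are available.

## Numerical choices and degenerate inputs

* Density tolerance `1e-7` (absolute); CDFs by trapezoidal quadrature on a
  2×10⁻⁴ s grid (normalization verified to 10⁻⁶ in tests).
* Zero-coherence trials have no correct answer; accuracy is assigned by
  seeded random designation and flagged `pseudo_accuracy`.
* Ratings outside 1..6, non-positive RTs, non-monotone trial indices and
  missing mandatory columns are structured validation errors naming rows.
* Constant series have no spectral slope (error); missing values must be
  explicitly dropped or interpolated (logged).
* Zero-variance ERN makes residualization return the centered Pe with a
  warning; fewer trials than bins is an error.
* All randomness flows from explicit integer seeds: the cohort generator
  seeds R's RNG once and derives per-trial simulator streams from it; the
  simulator uses its own counter-based generator so million-trial oracle
  runs are cheap and exactly reproducible.

## Problem sizes used by tests and the acceptance script

Oracle comparisons use $10^6$ trials per grid cell (step $10^{-3}$ s with the
bridge correction; one reference cell at $10^{-4}$ s). Parameter recovery
uses 25 participants × 500 trials at 4 chains × 2000 samples; the
confound-removal property 20 cohorts of 10 × 300 at 2 × 800; the EEG
analyses 16 × 400 at 2 × 1200. These sizes give stable group-level posteriors
for effects of the generated magnitude while keeping a full run on a single
CPU in the tens of minutes; they are the package's chosen study conditions,
and all of them are plain arguments if you want more.

## Known limitations

* The plain DDM omits inter-trial variability parameters; if real data carry
  strong drift variability, bound estimates partially absorb it.
* The confidence generator is one concrete post-decisional model; its
  thresholds are calibrated, not estimated, and participant differences in
  scale use are only caricatured by threshold-free rating noise.
* The sampler is random-walk based; posteriors with strong funnel geometry
  (tiny group variances) mix more slowly than HMC would — R-hat warnings
  flag this. DIC is reported because it is the conventional comparison here,
  with its known optimism about effective parameters.
* Between-experiment pooling is supported only as a baseline-bound shift
  (an experiment factor on $a_0$), not as full parameter-set duplication.
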