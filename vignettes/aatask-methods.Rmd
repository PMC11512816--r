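---
title: "Models and methods behind aatask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aatask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aatask` implements a complete analysis stack for approach–avoidance
decisions under manipulated action–outcome predictability, together with
a synthetic-cohort generator that emulates the statistical structure of
an elevator-style virtual-reality threat task.  This vignette explains
the models, the defaults and why they were chosen, and what the
synthetic data can and cannot establish.

## The task and the generator

Each simulated participant completes 4 blocks of 24 trials.  Within a
block, half the trials are *predictable* (the chosen elevator's occupant
is the post-choice outcome, deterministically) and half *unpredictable*
(the outcome avatar is redrawn with 50% threat probability); two-thirds
of trials present one angry and one neutral avatar (*threat* trials) and
one-third two neutral avatars.  Cell counts are exact, not stochastic,
and the angry avatar's side is counterbalanced within block and
condition.  A pre-stimulus jitter is drawn from a normal with mean 0.9 s
and SD 0.3 s; because its family and truncation are a free choice, we
truncate to [0.3, 1.5] s, which keeps the mean at 0.9 s and shrinks the
SD to about 0.28 s — the closest practical reading that avoids negative
waits.  Responses later than the 1.5 s deadline are recorded as
non-responses; with the default diffusion parameters these stay below 2%
of trials.

Choices and response times on threat trials come from an unbiased Wiener
diffusion process (below) with class-conditional parameters.  Two latent
behavioural classes are built in:

* the **goal-directed (GD) class** has a higher drift-rate toward
  avoidance in the predictable than the unpredictable condition, with
  cell avoidance targets 0.575 / 0.515;
* the **stimulus-response (SR) class** has one drift-rate in both
  conditions, higher overall, with targets 0.739 / 0.724, a slightly
  wider boundary (+0.11) and a shorter non-decision time.

Since the diffusion model's absorption probability at the avoidance
boundary is `1 / (1 + exp(-a v))`, drift-rates are set as
`v = logit(target) / a`, which makes the class-level avoidance rates
land on the targets by construction.  Boundary separation and
non-decision time (a = 1.12/1.23, t0 = 0.30/0.24 s) were fixed once so
that simulated RTs occupy the sub-1.5 s window with few non-responses;
they are plausible magnitudes for speeded binary choices, not estimates
of any particular dataset.  Between-participant heterogeneity is normal
scatter on (v, a, t0) with SDs (0.15, 0.06, 0.03) — a realistic level of
individual variation for this kind of task.  One consequence worth
stating plainly: at this class separation and 64 threat trials per
participant, class membership is *not* perfectly recoverable — the Bayes
error of classifying a participant from their choices alone is roughly
10%, so mixture-model class labels agree with the generating labels only
imperfectly (adjusted Rand index typically 0.5–0.8).  That is a property
of the study conditions, not of the estimator.

Neutral trials have no approach/avoid semantics; the side choice is an
unbiased coin flip and the RT comes from a condition-averaged diffusion
process, which keeps the Threat regressor of the physiological models
estimable.

### Physiological synthesis

ECG is generated at 1 kHz by placing Gaussian R-wave templates (SD 8 ms)
at beat times from an inter-beat-interval process: baseline heart rate
about 70 bpm, multiplicative IBI noise, slow heart-rate-variability
drift, and an event-locked deceleration kernel — a raised-cosine bump
supported from 1 s before to 4 s after stimulus onset, peaking at
+1.5 s.  The kernel gain depends on condition × trial type × class: GD
profiles decelerate more on predictable threat trials (−8 vs −4 bpm);
SR profiles decelerate equally (−5 bpm); neutral trials get −2 bpm in
both conditions.  P and T waves are omitted: R-peak detection only needs
R waves.  Trial onsets are spaced 15 s apart so −4..+10 s epochs never
overlap.

EMG is generated at 2 kHz per hand: a noise floor, a 50 Hz line
component (so the spectral-interpolation step is exercised), and one
Hann-windowed noise burst per responded trial centred at onset + RT on
the responding hand.  Burst amplitude is base + gain × threat, with the
threat gain nonzero only for SR profiles.

Subjective evaluations draw per-dyad avoidance and approach values from
normals with means 65.231 and 27.704 (SD 20.5), clamped to the 0–100
scale; the subjective value is `(avoid − approach) / 100`.

What the generator does *not* emulate: habituation or learning across
blocks, RT-dependent choice probabilities within a condition (the
unbiased diffusion process makes choice and decision time independent),
realistic ECG morphology beyond the R wave, movement artifacts, or
electrode drift.  Passing tests on synthetic cohorts therefore show that
the estimators recover what the generator planted under realistic noise;
they do not certify behaviour on recordings with artifact classes the
generator lacks.

## Behavioural models

Anticipations (RT < 150 ms) are removed before modelling; non-responses
are dropped separately.  Choices (avoid = 1) are modelled with a
hierarchical Bayesian logistic regression: condition treatment-coded
(unpredictable = 0), RT grand-average-centred, their interaction, and —
in class analyses — class treatment-coded (SR = 0).  Priors are
normal(0, 2.5) on coefficients and exponential(2) on random-effect SDs.
The random-effect structure is maximal over within-participant terms but
with *independent* (diagonal) random effects: the JAGS sampler used here
has no LKJ prior for the correlation matrix, and rather than substitute
a Wishart prior with different shrinkage behaviour we drop the
correlation structure and say so.  On the balanced designs this package
targets, the fixed-effect posteriors are essentially unaffected by that
choice.  Default sampling is 3 chains × 10,000 iterations with 2,000
warm-up; convergence is reported via split R-hat and effective sample
size, and model comparison uses WAIC computed from pointwise
log-likelihoods.

Per-parameter evidence uses the Savage–Dickey density ratio at zero
against the normal(0, 2.5) prior — chosen because it gives BF10/BF01 per
coefficient without bridge sampling; it is accurate when the posterior
density at zero is well estimated, and the implementation flags
summaries whose null-density estimate rests on few draws.

The simulation-based power analysis extracts fixed effects and
random-effect SDs, simulates cohorts at each candidate size, and refits
a frequentist mixed-effects logistic model (`lme4::glmer`, Wald z test);
a full Bayesian refit at 1000 simulations per sample size is not
desk-scale, and the Wald test on the simulated-data refit is the
conventional choice for this procedure.  Refit failures are counted
separately rather than as non-significant.

## Drift-diffusion models

The Wiener first-passage density is computed with the standard
small-time/large-time series expansion, switching regimes by comparing
the number of terms each needs at truncation tolerance 1e-7.  The start
point is fixed at a/2 and the diffusion coefficient at 1; avoidance is
the upper boundary.  No inter-trial variability parameters are included.
Two invariants anchor the implementation: the defective densities of the
two boundaries integrate to one, and the upper-boundary mass equals
`1 / (1 + exp(-a v))`.

The model grid mod1..mod8 crosses condition effects on v, a and t0.
Maximum-likelihood fitting uses multistart L-BFGS-B within bounds
v ∈ [−5, 5], a ∈ (0.3, 4], t0 ∈ [0, min RT), with AIC/BIC; trials with
RT ≤ t0 contribute a fixed log-density penalty of −25, which keeps the
objective finite while making such parameter values strongly
disfavoured.  The MCMC mode is a hierarchical
Metropolis-within-Gibbs sampler: participant-level (v, a, t0) around
group means, condition/class regressors estimated at the group level
only, DIC = D̄ + pD (pD = D̄ − D(θ̄)) and BPIC = D̄ + 2 pD.  Its priors
are mildly informative truncated normals (v ~ N(0, 2), a ~ N(1.5, 1),
t0 ~ N(0.3, 0.3), effect betas ~ N(0, 1), SDs half-normal(0.5)); the ML
path is the default for model selection and recovery work, with MCMC
used where posterior contrasts (differences of cell means, differences
of differences) are the target.

## Finite mixture modelling

Latent classes are found with an EM-fitted mixture of fixed-effect
logistic regressions of the best behavioural model
(intercept + condition + RT + condition:RT), with *participants* as the
mixture units: a participant's responsibility is computed from the
product of their trial likelihoods.  Whether the original grouped
mixture retained random effects within components is ambiguous;
fixed-effect components keep EM exact and the participant-level
grouping carries the heterogeneity the classes are meant to capture.
M-steps are weighted IRLS refits warm-started from the previous
iteration (a generalized-EM step that preserves the monotone
log-likelihood property), with up to 1000 iterations, relative
tolerance 1e-6, and 20 restarts by default (the first initialized from
a quantile split of per-participant avoidance rates, the rest from
Dirichlet-random responsibilities).  BIC uses the number of
participants as the sample size — they are the independent units — with
a trial-count alternative behind a flag; components are canonically
ordered by descending avoidance intercept so the "SR-like" component is
reproducibly first, and collapsing components (mixing proportion below
1/(10 n)) trigger a restart.

## Physiological preprocessing

ECG: 1–100 Hz zero-phase Butterworth band-pass; R peaks as local maxima
above 60% of the 99th percentile of positive amplitudes (quantile-based,
hence scale invariant — the per-recording calibration the original
procedure left unspecified) with a 250 ms refractory period; IBIs in ms;
IBIs differing more than 30% from the last accepted value are flagged
and replaced by cubic-spline interpolation; iHR = 60000 / IBI bpm (the
verbal description of this conversion in the source literature inverts
the ratio; the bpm reading is the only dimensionally consistent one);
beat-wise iHR is assigned at the closing R-peak of each interval,
linearly interpolated to 10 Hz, band-passed 0.01–2 Hz (order 2,
zero-phase; the series is mean-centred and reflection-padded first,
because the 0.01 Hz high-pass has a ~16 s time constant and would
otherwise leak edge transients into the recording), epoched −4..+10 s
around stimulus onset, and baseline-corrected with the −2..−1 s mean.
The closing-peak assignment makes the recovered deceleration peak lag
the true modulation by about half an IBI (~0.4 s at 70 bpm); this is a
property of the convention, documented rather than compensated.

EMG: 20–500 Hz band-pass, line noise removed by spectral interpolation
(±0.5 Hz around 50 Hz and harmonics up to 250 Hz, magnitudes linearly
interpolated from band edges, phases kept), full-wave rectification,
10 Hz zero-phase low-pass envelope.  Burst detection is single-threshold:
the baseline is the lowest-mean 500 ms window between 1 s pre-stimulus
and the response; bursts are runs above baseline mean + 3 SD, merged
when separated by less than 20 ms, discarded when isolated and shorter
than 25 ms; the RT-generating burst contains onset + RT.  Peak
amplitudes outside per-participant Tukey fences (1.5 IQR) are rejected.
Epochs are ±500 ms around the burst peak at 1 ms resolution.  The
analysed channel is the responding hand's, configurable.  Automated
participant-level quality exclusion drops participants losing more than
20% of trials.

## Time-resolved GLM and cluster-mass permutation inference

Z-scored epochs (one mean/SD per participant over all concatenated
samples) are fit per participant and time point by OLS with centred
±0.5 contrasts: condition (unpredictable −0.5), threat (neutral −0.5),
outcome (threat −0.5), response (approach −0.5), plus grand-centred RT
as a trial-level scalar regressor.  The Threat model is fit on all
trials and the Response/Outcome models on threat trials only, since
neutral trials have no response semantics.  Group inference thresholds
the one-sample t series at the two-sided p = 0.05 quantile; runs of one
sign longer than 100 ms (iHR) or 20 ms (EMG) are candidate clusters
summarized by their t-mass.

Significance uses the subset-zeroing permutation scheme implemented
literally: each permutation draws a subset size uniformly from 1..n,
zeros that many participants' beta series ("no effect"), and records the
largest absolute t-mass within the observed cluster windows; the
corrected p-value is the fraction of null draws exceeding the observed
absolute t-mass, floored at 1/n_perm.  Empirically this scheme is
conservative (family-wise error well under the nominal 5% on global-null
cohorts) while retaining high power for sustained effects, because
zeroing many participants both shrinks cluster means and — when few
noisy participants remain — occasionally produces large t spikes that
inflate the null.  The conventional participant-level sign-flip scheme
is available as an option; it re-detects clusters over the whole series
on every permutation and takes the maximum cluster t-mass (restricting
sign-flip nulls to the observed windows would be anticonservative, which
is why the option re-detects).

The trial-wise cardiac covariate is the signed maximum-magnitude
baseline-referenced iHR change within the significant negative intercept
cluster, Tukey-fenced and z-scored within participant, and feeds the
value-integration model: avoidance regressed on condition, centred RT,
iHR change, subjective value and all interactions up to the four-way
term.  Random slopes are restricted to intercept + condition by default;
the full four-way random structure is not identified at 64 trials per
participant.

## Problem sizes, tolerances and degenerate inputs

The package's tests exercise the full stack at reduced but
representative sizes: density normalization on a (v, a) grid against
1e5-draw simulation oracles; drift-rate recovery on 90-participant
two-class cohorts (±0.15 on group cell means); design recovery over 50
reduced simulations (12 participants × 64 trials each); mixture
K-selection over 50 cohorts of 90; permutation calibration over 200
global-null cohorts of 40 at 1000 permutations; and class-signature
detection over 5–10 cohorts per class (ECG at n = 40, EMG subsamples at
n = 15).  Diffusion simulation uses Euler steps with a Brownian-bridge
within-step crossing correction, which removes the leading
discretization bias; 1 ms steps are the default, relaxed to 5 ms where
only choice proportions matter (the bridge correction keeps those
unbiased at coarser steps).  Degenerate inputs error loudly rather than silently:
zero-variance covariates in the value-integration model, zero-SD
z-scoring, missing RTs in burst detection, non-positive IBIs,
cutoffs at or above Nyquist, empty trial tables.

## Known limitations

* Classes are recovered only as well as their behavioural separation
  permits (see above); mixture labels should be read as probabilistic.
* The subset-zeroing permutation scheme is conservative; where exact
  nominal error control matters, use the sign-flip option.
* The DDM MCMC sampler is a straightforward random-walk scheme tuned for
  the package's problem sizes; for much larger designs an HMC-based
  sampler would mix faster.
* Posterior correlations between random effects are not modelled.
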