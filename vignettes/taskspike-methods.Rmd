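---
title: "Analysing task-related spiking in a self-paced pedal-release task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing task-related spiking in a self-paced pedal-release task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taskspike)
```

## The task and the data model

`taskspike` analyses extracellular spike trains recorded while a head-fixed
rodent performs a self-paced, uncued pedal-release task. The animal starts a
trial by pressing both pedals into a holding area (0–30% of the range of
motion), holds them for at least 1 s, and then releases the left or the
right pedal; releasing the side that matches the current block rule earns a
liquid reward delivered 300–700 ms later (in 100 ms steps, at random).
Releasing the wrong side (error) or quitting the hold early (immature trial)
earns nothing. Blocks alternate between left- and right-rewarded rules once
performance criteria are met.

A *session* bundles the trial event table, both pedal position traces, all
spike trains with waveform durations, optional antidromic stimulation
events, and metadata — most importantly the recorded hemisphere, from which
contralateral/ipsilateral labels are derived at analysis time (they are
never stored). Sessions live on disk as a directory of TSV files with an
MD5 manifest, so fixtures are plain text, diff-able, and integrity-checked.

## The synthetic session generator

No public recordings exist for this task, so the package ships a generator
that produces complete sessions with ground truth. It is first-class,
tested code, and its defaults are the study conditions of the task:

* **Holding times**: 1 s minimum plus a truncated exponential (mean 0.8 s,
  truncated at 2 s extra), giving the 1–3 s holds typical of trained
  animals. The spread across holds is what the Hold/Go slope analysis
  exploits.
* **Trial counts**: 200 trials per session by default, a typical 2–3 h
  self-paced session; error and immature rates default to 10% each.
* **Block switching** follows the task rule: strictly more than 30 correct
  trials *and* 80% correct over the 10 most recent completed trials, or a
  forced switch at 100 rewards.
* **Pedal traces** are sampled at 1 kHz with smoothstep presses and an
  80 ms sigmoidal release, plus 0.3% Gaussian position noise, so the
  release-onset detector's 5%-excursion logic is genuinely exercised.
* **Neuron archetypes** are inhomogeneous Poisson processes: baseline plus
  event-locked kernels. `Hold` is a constant-slope ramp from hold onset to
  release — longer holds reach higher peaks, which is what makes the
  intersection slope −1. (A fixed-peak ramp would give a slope of about
  −0.3 and would not separate from Go cells; the constant-slope form is the
  one consistent with holding-time-dependent ramping.) `Go` is a Gaussian
  bump (sd 50 ms) at a fixed offset from release; by default half of the
  Go-like neurons peak at −225 ms (preparation) and half at +62 ms
  (feedback), mirroring the two phasic subpopulations around movement
  onset. `Reward` is a causal bump (centre +200 ms, sd 60 ms) after reward
  delivery on correct trials only. Combined archetypes sum kernels; the
  composed intensity is clipped at zero. Kernels are scaled by 0.5 on
  non-preferred-side trials, giving every task neuron a measurable but
  bilateral side preference.
* **Rates**: regular-spiking baselines default to 3 Hz (typical CA1
  pyramidal ongoing rates), fast-spiking to 12 Hz; kernel peaks default to
  4× baseline.
* **Collision physics**: projection neurons respond to untriggered
  (control) stimulation with an antidromic spike at their true latency
  (jitter sd 0.02 ms) unless a spontaneous spike fell within one conduction
  round-trip (2× latency) before the stimulus; spike-triggered (test)
  stimulations always collide. Trace troughs draw from N(−60, 5) with a
  spike and N(−5, 3) without, two well-separated populations for the ROC
  stage.

What the generator does *not* emulate: bursting and refractoriness, rate
drift, spike-sorting contamination, correlated noise across neurons, or
learning within a session. Passing tests on this generator therefore
demonstrate that the estimators recover the planted structure under
Poisson variability — not that they are robust to every pathology of real
recordings.

Everything is deterministic given the master seed: stage seeds are derived
from it, and an identical configuration reproduces sessions, ground truth
and report tables byte-for-byte.

## Task relevance and the five-type taxonomy

A neuron enters the analysis with at least 20 completed trials and 250
spikes. Task relevance is a Kolmogorov–Smirnov test of the pooled
event-aligned spike positions against uniformity on the analysis window
(release ±500 ms per side; reward onset to +1000 ms on correct trials),
with criterion p < 10⁻⁶. We use the deterministic one-sample form against
the uniform CDF (exact p for pooled counts ≤ 500); a two-sample variant
against one random uniform draw is available behind a flag but adds
test-side Monte-Carlo noise. The preferred side is the release side with
the smaller p value; exact ties (which occur only for degenerate inputs)
break toward contra.

Release-significant neurons whose smoothed PETH (σ = 12.5 ms) peaks at or
before release are split into **Hold** vs **Go** by the intersection-slope
procedure: preferred-side completed trials are divided into four
holding-time quartiles; the criterion level is 75% of the peak of the
all-trials 20 ms PETH; each range's PETH is scanned backward from its peak
to the interpolated time where it last rises through the criterion; and
the intersection times are regressed on the ranges' mean holding times.
Slopes at or below −0.5 are Hold, others Go. Release-significant neurons
peaking after release are the post-movement phasic subpopulation and are
labelled Go. Reward significance appends `&Reward`, or yields the pure
`Reward` type alone.

Numerical choices that matter here:

* Range PETHs are smoothed (Gaussian, default σ = 100 ms) before the
  crossing search. Smoothing a linear ramp is exactly shape-preserving away
  from its endpoints, so crossing-time *differences* — and hence the slope —
  are unbiased, while single-bin Poisson noise (which otherwise dominates
  with ~20 trials per range) is suppressed. At the default session size
  this choice brings the sd of the fitted Hold slope to about 0.14 around a
  mean of −0.93, with Go slopes within ±0.03 of zero.
* A range whose PETH never reaches the criterion before its peak is
  omitted (typical for the shortest-hold quartile of a ramp, whose peak
  rate is below 75% of the all-trial peak); at least two valid ranges are
  required, otherwise the fit is indeterminate.
* The slope threshold is applied to the signed slope, and the boundary
  value −0.5 is assigned to Hold.

## Activity indices

The peak bin is located on the preferred side's unsmoothed 20 ms PETH and
the same absolute peak period is reused on the non-preferred side.
Normalized activity is `SR_peak / SR_baseline − 1` with the baseline taken
at −1000 to −700 ms before release. The laterality index is
`(c − i)/(c + i)` when both normalized activities are positive, +1 when
only the contralateral one is, −1 when only the ipsilateral one is. When
neither is positive the index is undefined; such neurons are flagged and
excluded from laterality summaries rather than forced into a branch (task
neurons have a positive peak on their preferred side, so the case is rare
by construction). The reward-modulation index is
`(SR_r − SR_nr)/(SR_r + SR_nr)` over rewarded vs error trials, with peak
periods of peak ±250 ms for go-related activity and reward onset to
+500 ms for reward-related activity; on error trials, which have no reward
onset, the reward-aligned window is anchored at the release plus the
session's median reward delay.

## Time vs pedal coding (stepwise GLM)

For hold-related cells, the Gaussian-smoothed spike rate (σ = 150 ms) is
regressed on three within-trial predictors sampled on a common grid: left
pedal position, right pedal position, and trial time (seconds since the
most recent holding onset, reset at each onset). Selection is
forward–backward stepwise, entering terms at p < 0.05 and removing them at
p > 0.10 by F tests on the deviance change, from an intercept-only start
to a fixed point. The family is Gaussian with identity link — the response
is a continuous smoothed rate, which is what makes the F test the right
deviance comparison. Cells are classed Time / Time&Pedal / Pedal from the
final-model term p values under Bonferroni correction with factor 3 (the
number of candidate predictors). The default 20 ms grid is a deliberate
down-sampling: with 150 ms smoothing, finer grids change nothing but cost.
Smoothed-rate samples are serially correlated, and the reported p values
make no correction for this; the planted-recovery guarantees in the test
suite are statements about the selection procedure, not about the
calibration of those p values on autocorrelated noise.

## Latency clustering and pseudo-signal flow

Event-peak latencies (from σ = 12.5 ms smoothed PETHs) are clustered per
region with a Gaussian mixture. The component count is chosen by running
EM many times (1000 by default) for each count 1–5 and taking the count
with the minimum *mean* BIC (`−2 ln L + k ln n`); the reported fit is the
best-likelihood repeat at the chosen count. Each repeat starts from a
randomly seeded k-means partition: pure random-responsibility starts put
every initial component mean at the grand mean, a symmetric point EM
escapes too slowly, which silently inverts the mean-BIC penalty; the
k-means step is what makes repeats explore distinct local optima.
Averaging over restarts then penalizes over-parameterized mixtures, whose
surplus components often land in poor optima. Mixtures use free variances
(1D) and full covariances (2D), counted accordingly in the BIC; EM uses a
variance floor of 10⁻⁴ ms², a per-sample log-likelihood tolerance of 10⁻⁴
(the convergence semantics standard in mixture software — an absolute
total-likelihood tolerance makes over-parameterized fits crawl along flat
ridges to the iteration cap) and at most 500 iterations, with floored
repeats counted and reported. An x-means pass (BIC-driven k-means
splitting) provides an independent confirmation of the count.

Pseudo-signal flow draws, per bootstrap repeat, one neuron latency per
region and forms the lags `(CA1 − LECs, CA1 − LECd)`; 1000 repeats by
default. The lag cloud is clustered with the same 2D mixture machinery,
and each sample is labelled with one of the six firing orders of
{CA1, LECs, LECd} from the three pairwise lag signs. Exact zero lags are
broken toward the earlier-listed region in the order CA1, LECs, LECd —
an arbitrary but fixed rule that only matters on boundary sets of measure
zero. Samples with `lag_cs > 0` and `lag_cd < 0` sit in the
hippocampal-entorhinal quadrant (LECs → CA1 → LECd) and are flagged.

## Collision-test identification of projection neurons

Identification composes, in order: an ROC threshold on the window troughs
(Youden-optimal; when no labels exist, a two-means split provides
pseudo-labels first, and weak bimodality flags the threshold as
low-confidence); a pre-screen requiring at least 10 control events
classified as spikes; the inclusion gates — control spike probability
strictly above 50% and test spike probability below half of control; the
2×2 Pearson chi-squared collision decision at p < 0.05 (no continuity
correction by default, available behind a flag); the constant-latency test
(interquartile range of control spike trough times below 0.5 ms); and,
when paired-pulse data exist, frequency-following reliability of at least
0.8 at 100 Hz and 0.5 at 200 Hz (artifact thresholds — the test is
standard, its pass levels are not printed anywhere authoritative).
Latency is reported as the median trough time.

## Problem sizes and verification

The test suite verifies, among others: count conservation of every
unsmoothed PETH; < 0.1% smoothing mass loss away from edges; slope −1 ± 0.05
on deterministic linear-ramp spike trains (a closed-form oracle); null
calibration of the relevance index on 1000 homogeneous Poisson neurons
(zero false positives at 10⁻⁶, uniform p distribution); ≥ 90% exact
archetype recovery on a 120-neuron cohort with ≥ 95% correct Hold/Go slope
signs; mixture-count consistency in ≥ 95% of 100 seeded runs for
1-component and 5-sd-separated 2-component samples (n = 200, 100 EM
repeats per count; the full 1000-repeat protocol is the default in
analysis code); ≥ 90% diagonal recovery of planted Time/Pedal/Time&Pedal
responses at signal-to-noise 5 over 100 seeds; ≥ 95% of simulated
projection neurons passing and ≥ 99% of non-projection neurons failing the
composed collision criteria; and byte-identical report tables across two
pipeline runs at a fixed seed. Cohort sizes in the suite (120 neurons,
100–200 trials, 300–1000 bootstrap repeats) were chosen as the smallest
sizes at which these guarantees are statistically meaningful.

## Known limitations

* The Hold/Go slope estimator needs holding-time spread; sessions with
  near-constant holds make every range cross at the same time and the
  slope degenerates.
* The laterality index is undefined for neurons suppressed on both sides;
  they are flagged, not imputed.
* GLM p values inherit the serial correlation of the smoothed rate (see
  above).
* The generator's archetypes are idealized kernels; recovery rates on real
  data will be lower than on synthetic cohorts, and the package makes no
  claim otherwise.
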