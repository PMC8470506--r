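---
title: "perturbreach: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perturbreach: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbreach)
```

# The task and the stated world

The package simulates and analyses a reach-to-grasp task in which a target
bar can rotate 45° clockwise (CW) or counterclockwise (CCW) 70 ms after the
hand leaves a central holding pad. One testing block has four sets: 90
unperturbed trials to targets fixed at 45°/90°/135° (balanced over two
target sides, three trials per side in every consecutive group of six); 90
trials with the 90° target *randomly* perturbed CW, CCW or not at all (one
third each); and two 30-trial sets in which the perturbation direction is
*repeated* on every trial, so it becomes predictable. The trial clock is
zero at pad hit; the cue light follows a ≥ 300 ms hold, movement begins
after a lognormal cue reaction time (mean 250 ms, sd 50 ms), movement times
average 270 ms unperturbed and 400 ms perturbed, and the perturbation occurs
exactly 70 ms after release. A stated alternative latency of ~130 ms after
movement initiation exists in the task description; the generator uses
70 ms, which is the figure used everywhere else, and keeps the latency
configurable (`perturbation_latency`).

Everything downstream is tested against this generator, whose ground truth
is known exactly. That is the point of the package — and also its main
caveat: a green test establishes that the analysis recovers the generator's
world, not that the generator is a complete account of real M1 data.

# Behaviour: trajectories and the reaction-time estimator

Hand orientation is modelled as minimum-jerk segments sampled at 100 Hz.
On perturbed trials the hand first heads for the initial (90°) orientation;
a corrective minimum-jerk segment toward the final orientation starts
`true_rtp(k)` after perturbation onset, with
`true_rtp(k) = rtp_floor + (rtp0 − rtp_floor)·exp(−k/τ)` on repeat trials
(defaults `rtp0` = 100 ms, `τ` = 3 trials, floor = −20 ms, i.e. late
corrections begin *before* the perturbation) and a constant 100 ms on random
trials. The correction transiently over-rotates past the target by 10° (its
amplitude decays over repeat trials) and lands exactly on the final
orientation at target hit.

Additive noise is smooth (≈ 20 ms correlation time) with a marginal sd of
0.15°. This models *measurement* noise of an optical tracker
(≈ 0.1 mm marker jitter over a ~10 cm marker base), not biological
trial-to-trial path variability, which is deliberately absent: the
reaction-time detector compares single trials against a band built from
unperturbed trials, and only at tracker-level noise does the band-deviation
definition resolve a 100 ms delay. With realistic movement variability the
same estimator would carry a much larger, path-variance-dominated lag.

The estimator itself: build the pointwise mean ± 1.96 sd band of the
unperturbed 90° trajectories on a 10 ms grid aligned to release
(`build_band`); the deviation time is the first time ≥ release at which 3
consecutive samples fall outside the band **on the side of the new target
orientation**; RTp is that time minus perturbation onset. A normal-range
band is the default rather than a confidence band of the mean: a single
trial is being compared, and an SEM band would shrink with the number of
reference trials and over-detect (the SEM variant remains available,
`type = "sem"`). The persistence rule (k = 3 samples) suppresses
single-sample noise crossings; the directional requirement stops
over-rotation of the primary movement from counting as a correction. None
of these three construction details are fixed by the task description;
all are exposed as arguments.

Known bias: a minimum-jerk correction leaves the band gradually, so
detection lags onset by ~15–20 ms at the default noise level (measured:
mean estimated RTp ≈ 102–107 ms for a true 100 ms delay, well inside the
±20 ms acceptance tolerance; noiseless bias ≤ one sample). The same lag
means late repeat trials with a true −20 ms delay estimate near 0 ms —
"close to zero" rather than reliably negative.

# Spikes: the intensity model

Each unit's conditional intensity is a sum of non-negative components
(clipped at zero), sampled by Lewis–Shedler thinning:

* baseline (constant);
* a movement transient: Gaussian bump centred 135 ms after release
  (sd 90 ms), *identical across conditions* — this matters because the
  statistical tests below compare duration-matched windows, and a
  condition-dependent movement transient would break their null;
* a corrective burst on perturbed trials: Gaussian centred 250 ms after
  release (sd 60 ms); height `corrective_gain_random` on random trials and
  `corrective_gain_repeat·exp(−(k−1)/c)` on repeat trials — the burst fades
  as the perturbation is learned;
* an anticipatory ramp on repeat trials only, rising from the cue light to
  perturbation onset and relaxing over 100 ms, scaled by
  `1 − exp(−k·learning_rate)` and by tuning to the *anticipated* final
  orientation;
* tonic cosine orientation tuning (optionally sharpened:
  `(½(1+cos))^tuning_power`) and a target-side term, active from cue light
  to target release.

Two modelling decisions deserve justification:

**Tuning follows the displayed orientation, shifted by anticipation.**
Before perturbation onset a unit is tuned to the orientation actually shown
(90°); after onset, to the final orientation. On repeat trials the
pre-perturbation tuning shifts toward the anticipated final orientation in
proportion to learning — the unit plans toward a target orientation not yet
present, which is exactly the interpretation demanded by negative reaction
times. A unit tuned to the *future* orientation on random trials would be
clairvoyant; the cross-test below depends on ruling that out.

**Tonic components stay on through the grasp hold.** If orientation or
direction tuning switched off at target hit, a unit defined as
perturbation-insensitive would still be flagged perturbation-responsive
simply because perturbed movements last ~130 ms longer (more tonic spikes in
the response window). Sustained hold-related activity resolves the
contradiction between such a unit's ground-truth label and its measured
behaviour.

# Epoch statistics

Epochs per trial: CHT `[pad hit, light on)` — the baseline; RTc
`[light on, release)`; MT `[release, hit)`; PD `[release, perturbation)`;
PR `[perturbation, hit)`; THT `[hit, target release)`. Spike counting is
half-open `[start, end)`. The task description defines CHT as running to
target release, which would overlap every other epoch; as the baseline it
must precede the cue, so the package uses the holding phase. The baseline SD
in the 2-SD task-related rule is the across-trial SD of the CHT rate (the
only SD defined for one scalar per trial).

The perturbation-response test compares PR-epoch rates on perturbed trials
of one schedule against rates of unperturbed-90° trials over a
*duration-matched* window starting 70 ms after release. Matching the window
(rather than using each unperturbed trial's own, shorter, MT) makes the
movement transient cancel in expectation, keeping the null false-positive
rate at α; the mismatch variant inflates it to ~70 %. The anticipatory test
is one-sided (repeat > unperturbed, the direction the phenomenon is defined
by) on the fixed `[release, release+70 ms)` window. All *t*-tests are
pooled-variance (the era's default; Welch available via `var_equal`), no
multiple-testing correction is applied anywhere (matching the original
analysis), and the baseline-stability filter runs all six pairwise set
comparisons uncorrected — deliberately strict, with a familywise exclusion
rate of ~26 % under the null, which is verified by simulation in the test
suite. The 2 × 3 ANOVA (direction × orientation, unperturbed trials,
15 per cell) is sequential (Type I) if the input is unbalanced.

# The population preset

The `paper_mixture` preset allocates task-related units as 293 : 315 :
235 : 42 out of 885 into: corrective-under-random only (`corrective_only`),
corrective under both schedules (`mixed`), repeat-corrective plus
anticipatory (`corrective_anticipatory`), and perturbation-insensitive
direction-tuned units (`direction_tuned`). The last group cannot be
orientation-tuned: a unit tuned to the displayed orientation necessarily
responds when the orientation jumps, so it could not be "unperturbed only".
Gains are fixed per class (burst 60/40 Hz, ramp 25 Hz, learning rate 0.35,
movement 20 Hz) with baselines uniform on 5–12 Hz and preferences drawn at
random; class counts are deterministic (largest remainder).

One recovery quantity is structurally on its tolerance boundary: with a
latent anticipatory fraction of 235/885 = 26.6 %, near-complete test power
(strong gains) and a 5 % one-sided false-positive floor on the remaining
73.4 % of units, the *expected* flagged fraction is
`0.266·~0.98 + 0.05·0.734 ≈ 30 %`, against a 27 ± 3 point criterion. The
package reports whatever the pipeline measures (≈ 28.8–31.3 % across seeds);
no parameter is tuned to move it.

# The decoder

Features are per-trial binned firing rates over `[−300, +500] ms` around
release. The default bin is 200 ms: at single-trial rates a 20 ms bin holds
0–2 spikes, and forty such features against ~45 training trials make the
network memorise its training half and generalise at chance; four features
at the component timescales do not. (20 ms remains available — and remains
the PSTH bin.) Left- and right-target trials are analysed separately.

The network is the classical two-layer backpropagation architecture: inputs
z-scored with training-set statistics only, a tanh hidden layer (5 units), a
single linear output coding −1 / 0 / +1, full-batch gradient descent on the
training-half mean squared error (same minimiser as the sum squared error;
lr 0.05, 1500 epochs — chosen for reliable convergence, with the loss trace
retained so monotonicity is testable). Because a handful of training trials
leaves a single network's raw output noisy, `decode_unit` averages 15
independently initialised networks; each member is exactly the base
architecture. The decision rule: output ≤ −0.6 → class −1, ≥ +0.6 → +1,
|output| ≤ 0.4 → 0, and the dead zones (0.4, 0.6) yield *no decision*,
counted incorrect — the printed ±0.6 boundaries are preserved and the zero
region is the symmetric complement. Splits are stratified 50/50 with a
6-per-class test set (18 trials).

The exemplar unit (`neuron_preset("strong")`) represents the top of the
single-unit decoding distribution in a fully adapted session: burst 250 Hz
under random perturbation, repeat burst fading within a trial, anticipatory
ramp 80 Hz saturating by the second repeat trial, sharp (exponent-4)
orientation tuning of 120 Hz preferring 135°, baseline 5 Hz. Sharp tuning
with the preference at the edge of the tested range maps the three task
orientations onto monotone, well-separated rate levels — which is what a
single scalar output decoding three classes at 17/18 requires. These
parameters are at the upper edge of plausible M1 physiology; an ideal
observer given the true intensities classifies at 97–98 %, so the stated
performance is estimator-limited, not world-limited. Most units (any of the
population preset's classes) decode far lower, reproducing the low / fair /
high clustering: corrective-only units separate perturbed from unperturbed
but not random from repeat; only corrective + anticipatory units reach the
high cluster.

The cross-test feeds random-perturbation trials to the direction-task
network of a unit whose modulation exists only in the repeat-trial
anticipatory ramp, with features restricted to the pre-perturbation window
`[−300, +70] ms`. Random trials are then feature-identical to unperturbed
ones, outputs sit near zero, never beyond ±0.6, and the correct rate
against ±1 labels is zero. Unperturbed trials interleaved in the random set
are excluded from this cross-test (they carry label 0 and would score
"correct" trivially); how the original analysis scored them is unstated.

# Numerical and degenerate-input conventions

Zero baseline SD in the 2-SD rule: floored at 1e−8 and flagged. Two
zero-variance samples in a *t*-test: p = 1 if means agree, else 0. Empty
ANOVA cells: error (the unit is skipped and logged upstream). Band
half-width: floored at 1e−6°. Zero-variance features: left unscaled.
A final partial feature bin is normalised by its own width. Ensemble
members consume the RNG stream sequentially, so one seed reproduces the
whole decode. All randomness flows through R's RNG: a seeded run is
bit-reproducible end to end.

# Limitations

* Trajectories carry tracker noise only; no biological path variability, no
  3-D transport, no velocity-profile analysis.
* Spike trains are inhomogeneous Poisson: no refractoriness, no history
  dependence, no trial-to-trial gain correlations.
* Learning is a fixed exponential in the within-condition trial index; no
  day-to-day carry-over, no forgetting, no failed trials by default.
* The anticipatory-fraction recovery sits on its tolerance boundary for the
  structural reason given above.
* The RTp detector's band-crossing lag (~15–20 ms) means truly negative
  late-repeat delays are reported as ≈ 0.
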