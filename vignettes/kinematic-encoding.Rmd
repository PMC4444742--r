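---
title: "Methods: kinematic encoding analysis and the synthetic-session model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kinematic encoding analysis and the synthetic-session model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinencode)
```

This vignette documents the scientific and numerical choices behind
`kinencode`: the encoding analysis itself, the control-theoretic generative
model used to validate it, and the places where the design was genuinely
open and a decision had to be made.

## The data model

A session consists of 2D head-position tracking (mm, nominally 30 frames/s,
x rightward and y upward in the animal's frame), per-unit spike timestamp
lists with metadata (hemisphere, mean rate, spike width), and task events
(cue onsets, outcome times and types, optional optogenetic stimulation
trains). All times are seconds from session start. A configuration flag
`camera_mirrored_x` flips x at load for camera-facing-the-animal recordings,
because left/right lateralization statements are animal-centric.

Tracking dropouts are handled by masking, not interpolation: gaps longer
than 3 nominal frame intervals become invalid bins, excluded pairwise from
every correlation (and propagated through the differentiation stencils they
touch). How dropouts were handled in the original recordings is not
documented anywhere we could follow; masking is the conservative choice
because fabricating kinematics across a dropout would inject spurious
low-frequency correlation.

## Kinematics

Position is linearly interpolated onto a uniform grid (default bin width
0.030 s, the bin size used for all joint neural/behavioral analysis),
optionally smoothed with a centered 3-bin moving average, differentiated by
central differences to velocity, and the velocity differentiated again to
acceleration. The rectified split then yields the eight directional
variables.

Numerical choices worth stating:

* **Central differences** have zero phase shift. A forward difference
  would advance the velocity estimate by half a bin and bias every lag
  estimate downstream; this matters because the lag *is* one of the
  scientific outputs.
* **Bin first, then differentiate.** The alternative (differentiate at the
  native 33.3 ms frame interval, then rebin) is nearly equivalent for
  smooth trajectories; we resample first so that all series live on one
  grid from the start and masks are well defined.
* **Smoothing (default 3 bins, disableable)**: second derivatives of raw
  30 fps tracking are noise-dominated; a short centered window attenuates
  frame jitter without phase error. The window is exposed in the API
  rather than hidden.
* **Acceleration as the difference of the velocity series** (not the
  direct second difference of position). The two agree except at mask
  edges; differencing velocity makes mask propagation compositional.
* **Translation invariance by construction.** Coordinates are centered on
  the first sample before interpolation, smoothing and differentiation, so
  a constant offset of the whole trajectory cannot leak into velocity or
  acceleration through floating-point rounding. (With inputs quantized so
  that the shift is exactly representable, the components are bit-for-bit
  identical under translation; the test suite checks exactly that.)
* The first/last bins of any differentiated series use one-sided stencils
  — a different estimator — and are therefore excluded from
  derivative-based correlations.

For optogenetic stimulation epochs, distance is the Euclidean displacement
of the LED between train onset and train termination, and speed is the
derivative of the instantaneous distance from the onset location; the
within-train grid includes the termination sample so the distance is
evaluated exactly at the end of the train.

## The two-step encoding analysis

For each unit and each of the eight variables, on the full session:

1. **Lag scan**: Pearson r between `rate[t]` and `kin[t + ℓΔ]` for integer
   lags `ℓ ∈ [−L, +L]`, on the jointly valid overlap recomputed at each
   lag. The lag maximizing `|r|` wins. Positive lag means kinematics
   follows the neural signal.
2. **Shifted Pearson**: r on the aligned overlap, two-sided p from the t
   transform with n − 2 degrees of freedom.

The unit's class is the variable with the largest `|r|` among those with
p < α (default α = 0.05, per variable, no multiple-comparison correction —
a deliberate replication of the published procedure; an optional
circular-shift permutation p, `null = "shuffle"`, is provided for honest
inference on autocorrelated sessions, since the parametric p is
anti-conservative there).

Open choices and how they were resolved:

* **Search window** (`max_lag_s`, default 0.5 s = ±16 bins): the
  literature reports neural–kinematic lags of roughly 20–160 ms; ±0.5 s is
  generous without admitting spurious far-lag maxima.
* **Maximize `|r|`, not r**: pause-like units correlate negatively, and
  classifying them requires the magnitude. The sign is reported
  separately.
* **Tie-break** at equal `|r|` (within 1e-12 absolute, which also absorbs
  floating-point ties on degenerate collinear signals): smallest `|ℓ|`,
  then the negative member — deterministic output, with a mild preference
  for the neural-leading convention reported for burst units.
* **Zero variance** on an overlap (e.g. a direction never visited, or a
  constant-rate unit) yields an undefined correlation, treated as
  non-significant; a unit with no significant variable is `uncorrelated`.
* **Peri-event analyses** concatenate the valid bins inside the event
  windows across trials. On synthetic units with stationary coupling,
  session-wide and peri-event-only classification agree in ≥95% of cases,
  which is the internal-consistency check that the session-wide
  correlation is not an artifact of event timing.

### Opponency

The two rectified halves of an axis are never simultaneously positive, so
at any common shift `cov(k_up, k_down) = −E[k_up]·E[k_down] < 0` whenever
both directions occur: a unit positively coupled to one direction must
show a negative correlation with the opposite direction *at the same
alignment*. The `opponency()` summary therefore compares the two
directions of the class axis at the unit's operative (class) lag. Letting
each direction choose its own best-|r| lag is not the same comparison: on
task sessions the opposite direction's scan legitimately locks onto the
*return* movement half a second later and can report a positive r there.
Both views are available (the per-variable table keeps own-lag records;
`r_aligned` holds the same-shift values).

### The GABA-derivative relationship

Nigral GABAergic output neurons carry position-like signals and DA neurons
velocity-like signals, so for a matched pair the time-derivative of the
GABA rate should mirror the DA rate (negative peak correlation near zero
lag). `gaba_da_derivative_test()` differentiates the GABA rate by central
differences and runs the same two-step analysis against the DA rate. Two
numerical points:

* The construction `gaba = −Δ·cumsum(da)` is an exact discrete
  antiderivative; with the edge bins excluded, a linear-ramp `da` gives
  r = −1 at lag 0 to machine precision, which the tests assert at 1e-9.
* The central-difference derivative of a *raw* 30 ms Poisson rate is
  dominated by counting noise (differencing amplifies it by 1/(2Δ) ≈ 17).
  `smooth_sigma_bins` (default 0) applies a Gaussian kernel to both rates
  before differentiation; ~3 bins (90 ms) makes the relationship visible
  in Poisson pairs at realistic rates. The default stays 0 so the exact
  identity above is preserved.

## Population statistics

The 2×2 chi-square (lateralization, valence) uses no continuity
correction, matching the style of the published statistics; Yates
correction is behind a flag. Firing-rate comparisons across classes use
one-way fixed-effects ANOVA; lag asymmetry between positive and negative
units uses a Welch t-test on |lag|. Identical-everywhere inputs are a
degenerate case where both the effect and residual sums of squares vanish;
the package reports F = 0 (no evidence of an effect) rather than NaN.

The stimulation analysis is a fixed-effects two-way ANOVA
(genotype × frequency) on session-level summaries of peak speed and
distance. The published analysis was described as repeated measures, but
the session-to-animal assignment needed for that model is not part of our
data model; the fixed-effects simplification on session summaries is
documented here, and a blocking factor can be added by the user on the
summary data frame.

DA vs non-DA cell classification (low rate and wide spike ⇒ DA) has no
published numeric boundaries; the defaults (12 Hz, 0.5 ms FWHM) are
conventional for nigral recordings and exposed in `cell_class_rule()`. The
synthetic populations are generated well-separated, so tests do not depend
on the exact cutoffs. The spike/noise isolation ratio of sorted units is
carried as metadata only — there are no waveforms in the data model.

## The synthetic-session generator

The generator exists so that every stage of the analysis can be validated
by parameter recovery; its defaults are the study conditions, not tuning
knobs.

**Trajectory model.** Per axis, at step `dt` (default 5 ms):

```
error  = da_gain · (v_ref − v_sensed)
p_ref += dt · (error − integrator_leak · (p_ref − home))
v      = position_gain · (p_ref − p)
p     += dt · v
v_sensed = v + noise
```

A velocity controller sits above a position controller: the velocity
error, scaled by a multiplicative DA-like gain, is integrated (leakily)
into the position reference of the lower loop. Zero DA gain ⇒ no movement;
larger gain ⇒ faster movement (strictly monotone peak speed in the tests);
the leak returns the system to its home position after each bout, which is
also what the animal does. With `opponent_split` the error is phase-split
into a non-negative direct and non-positive indirect channel whose sum
equals the raw error at every step. Stability requires
`position_gain · dt < 2`, enforced at construction. The leak acts on the
position reference relative to a fixed home coordinate; with zero gain the
reference then decays exponentially at exactly the leak rate, which gives
the closed-form check used in the tests. The cascade's slow mode decays at
roughly `leak / (1 + da_gain)`.

**Task structure.** Defaults: 60 trials, 100 ms tone, outcome 1.9–2.1 s
after tone offset, 20–50 s ITIs, sucrose/air-puff schedules (AB or ABAB).
Movement bouts are raised-cosine velocity-reference pulses (smooth and
twice differentiable, so acceleration components are well defined):
cue- and outcome-locked bouts toward the spout (away from it for air
puff), with Gaussian direction jitter (sd 0.5 rad) and ±30% amplitude
jitter reflecting trial-to-trial path variability, plus spontaneous
random-direction ITI bouts at 0.08 /s (~5 per minute — unrestrained mice
move frequently, and most of the session is ITI). The direction diversity
matters: without it the cue/outcome bouts all run along one diagonal and
the rectified components of the two axes become nearly collinear, which no
classifier — including the real analysis — could distinguish.

**Units.** Intensity `λ(t) = max(0, baseline + sign·gain·target(t + ℓΔ))`
evaluated per 30 ms bin, Poisson counts per bin, timestamps uniform within
the bin (exact under the analysis binning). The rate *leads* its kinematic
target by the planted lag, as burst units lead movement, so the planted
lag is recovered as +ℓ bins under the analysis sign convention. The
left-edge target value is used for the bin's intensity; empirically this
is phase-unbiased under the analysis (a mid-bin target shifts recovered
lags by +half a bin). Negative-sign units floor at zero during movements —
that flooring *is* the pause. Gains are calibrated per unit by inverting
`r = g·sd(k) / sqrt(g²·var(k) + mean(λ)/Δ)` so each unit's expected
correlation lands in a requested band (default 0.35–0.55, matching the
strength of observed unit-kinematics correlations).

**Cohorts.** Class composition defaults to the recorded-population
template (velocity:acceleration 66:31 among classified units, per-cell
direction counts 18/19/13/16 and 9/13/4/5, ~8.5% uncoupled, 78% positive
sign). Positive units get lags of 0–1 bins and negative units 5 bins
(~150 ms), mirroring the reported short positive and long negative lags.
Horizontally tuned units sit contralateral to their preferred direction
with probability `contralateral_bias` (default 0.75; 0.5 is the null).
Each cohort also carries GABA/DA pseudo-unit pairs (GABA coding −y
position at 25 Hz baseline, DA coding upward velocity) for the derivative
test.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tracking noise and lens distortion (positions
are exact up to 30 fps sampling), z-axis movement, nonstationary coupling
(satiety, drift), spike-sorting contamination, bursty non-Poisson firing
statistics, and any reward-prediction component of DA activity. Recovery
results validate the *pipeline*, not the biological claim.

## Problem sizes and calibration

The test suite and the acceptance script use the fast task profile
(10 trials, 5–10 s ITIs, ~100 s of session) — chosen to exercise every
code path at sizes where the statistical properties are already stable.
End-to-end recovery is scored on a 100-unit cohort (expected: class
accuracy ≥ 0.9, sign accuracy ≥ 0.95, median lag error 0 bins; observed in
practice ≥ 0.95 class accuracy). Lags recover with median error 0
throughout the calibrated correlation band, and exactly per unit at strong
coupling (|r| ≳ 0.85); near the band's center an occasional ±1-bin error
remains, as expected for a correlation peak flat over one bin. Type-I
error of the lateralization chi-square and of the stimulation ANOVA is
calibrated on 2,000 null replicates of the layers those tests actually
consume (the categorical cohort composition and the session summaries
respectively — the test statistic's null distribution is identical to the
full spike-level simulation at a tiny fraction of the cost). Session-level
stimulation summaries default to sd 1.2 mm/s because each summary averages
many trains; at that dispersion a 2 mm/s genotype effect is detected with
~90% power at ~20 sessions.

## Known limitations

* The parametric Pearson p ignores temporal autocorrelation and is
  anti-conservative on long sessions; the default replicates the published
  procedure, and the shuffle null is the honest alternative.
* Classification among correlated components (e.g. a velocity component
  vs its own acceleration) is winner-take-all on |r|; near-ties are
  genuinely ambiguous and small rate fluctuations can flip them.
* The control model is the simplest faithful realization of the cascade
  hypothesis (proportional loops, one leaky integrator, multiplicative
  gain); it is a validation harness, not a biophysical model.
* `read_session`/`write_session` use plain CSV/JSON; vendor acquisition
  formats and video are out of scope.
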