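---
title: "Analysing fictive locomotion, gait kinematics, and locomotor recovery with locokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fictive locomotion, gait kinematics, and locomotor recovery with locokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(locokit)
```

## The analysis problem

Isolated spinal cord preparations produce "fictive" locomotion: rhythmic,
alternating bursts in flexor-related (upper lumbar) and extensor-related
(lower lumbar) ventral roots, typically near 1.2 Hz when evoked
pharmacologically. Three questions recur when characterizing how an
interneuron population relates to this rhythm: *when in the step cycle
does the cell fire*, *when does it receive synaptic input*, and — after a
spinal lesion — *how much locomotor function returns with training*.
locokit implements the complete quantitative chain for all three,
together with generators that synthesize inputs with known ground truth.

## Double-normalized cycle phase

A locomotor cycle runs from one extensor-burst onset to the next and
contains one flexor-burst onset. Because the two phases have different
and variable durations, times are mapped to a *double-normalized* phase:
the extensor phase is linearly stretched onto [0, 0.5) and the flexor
phase onto [0.5, 1). Phase 0 therefore always marks extensor onset and
phase 0.5 flexor onset, so cells and synaptic events can be compared
across cycles and preparations regardless of duty cycle. All intervals
are half-open: a spike exactly at a cycle boundary belongs to the next
cycle, and a mean phase of exactly 0.5 classifies as flexor.

Burst extraction proceeds in two steps. `rectify_integrate()` subtracts
the median (a robust baseline), full-wave rectifies, and smooths with a
centred moving average (default window 50 ms; a leaky integrator would
serve equally, but the moving average has an exactly known edge
behaviour, which the tests exploit). `detect_bursts()` then applies
hysteresis thresholding: a burst is a run above the *off* threshold that
reaches the *on* threshold, with defaults of 50% and 30% of the
95th-percentile envelope value. The percentile, rather than the maximum,
makes the thresholds robust to stimulation artifacts. Candidate cycles
with zero or multiple flexor onsets (e.g. brief extra flexor bursts
during extension) are discarded and counted rather than silently
repaired, and cycles whose period departs from the median by more than a
factor of three are flagged as outliers and excluded from phase analysis
by default.

## Circular statistics and the subsampled Rayleigh rule

Spike phases φ are treated as angles θ = 2πφ. The mean phase Φ is the
direction of the resultant of the unit phase vectors and the angular
concentration r is its length: r = 1 when the cell fires at precisely
the same phase each cycle, r = 0 for uniform dispersion. Significance of
phase locking uses the large-sample Rayleigh approximation
p = exp(−n·r²). Two design decisions deserve note:

* **Why the simple exponential form.** The finite-sample corrected
  series is available (`rayleigh_p(..., corrected = TRUE)`), but the
  classification rule uses the plain form because the conventional
  display threshold for 50 spikes — r = 0.24 — is exactly the inversion
  of the plain form: r* = √(−ln α / n) = 0.2448 for n = 50, α = 0.05.
  Classification always compares against the full-precision threshold;
  the rounded 0.24 is exported separately (`r_threshold_50`) for display
  parity with polar plots.
* **Why subsample to 50 spikes.** r is biased upward at small n and its
  null distribution depends on n, so cells recorded for different
  durations are not comparable at their raw spike counts. Drawing
  exactly 50 spikes without replacement puts every well-sampled cell on
  the same footing; cells with 50 or fewer spikes are used whole, with
  the threshold recomputed for their actual n (so rhythmicity can still
  be demonstrated, just against a stricter threshold). The draw requires
  an explicit seed — the subsample is part of the reported result, so it
  must be reproducible.

Left–right (or flexor–flexor) coordination uses plain single-segment
normalization of one root's onsets within the other root's cycles,
summarized by the same circular statistics; strict alternation gives
Φ ≈ 0.5.

## Synaptic-event detection and phase histograms

Postsynaptic currents are detected by sliding scaled-template matching.
The template is a difference of exponentials,
w(t) = (1 − e^(−t/τ_rise))·e^(−t/τ_decay), peak-normalized, with
defaults τ_rise = 1 ms, τ_decay = 5 ms, duration 30 ms — generic fast
PSC kinetics. At every offset the template is fitted with an optimal
scale and additive offset; the detection criterion is scale / SE(fit),
thresholded at 3.5 (standard template-matching practice). Because the
template peak is 1, the fitted scale *is* the event amplitude. Two
guards keep the criterion honest: fitted scales at the numerical
resolution of the trace are ignored (otherwise an exactly flat baseline
produces spurious infinite-criterion hits), and a candidate falling
inside the extent of an already accepted event with less than 10% of its
amplitude is treated as a re-fit of that event's decay tail. Polarity is
a required argument: at a −40 mV holding potential, IPSCs are outward
(positive) and EPSCs inward (negative) deflections, and the convention
is never inferred from the data.

Event times are mapped to cycle phase and binned into 50 equal bins;
percentages are reported against the uniform expectation of
100/50 = 2% per bin. `average_cycle_envelope()` resamples the root
envelope onto the same bin grid for overlay — a plotting aid, not a
statistic.

## Kinematics

Joint angles are interior angles at each marker triplet. The knee is
*not* taken from a skin marker: skin slides over the knee during
locomotion, so the knee is reconstructed geometrically as the
intersection of circles of radius femur around the hip marker and
radius tibia around the ankle marker. Of the two intersections, the
`"anterior"` branch (greater x, the direction of travel) matches
side-view rodent limb geometry and is the default; the branch is an
explicit argument recorded in outputs, never guessed. Frames where
|hip − ankle| exceeds femur + tibia raise an error naming the offending
frame, since that indicates wrong segment lengths or tracking failure.

Stance onsets are local maxima of the horizontal toe position (the toe
is farthest forward at touchdown), with a minimum prominence (default
10% of the trace's peak-to-peak excursion) and minimum separation
(default 100 ms) to reject jitter; swing onsets are the minima between
consecutive stance onsets. Each step cycle is then resampled to 100
points. The fixed 100-point budget is split 50/50 between stance and
swing rather than proportionally: equal per-phase allotment aligns
stance/swing landmarks across steps with different duty factors, which
is what averaging joint-angle profiles requires. Proportional allotment
is available by resampling the whole cycle instead
(`points_per_phase` is configurable); the 50/50 default is the
documented choice.

Slope comparisons (e.g. stance duration against cycle period between
genotypes) use a pooled linear model with a group × predictor
interaction — analysis of covariance on slopes — and report the
interaction p-value.

## Step ratio and Hill recovery fits

After complete spinal transection, recovery is indexed by the
hindlimb/forelimb step ratio: hindlimb steps (any forward toe excursion,
counted with a hysteresis of 0.1 cm so that minimal movements count but
tracking jitter does not), averaged between hindlimbs, divided by
forelimb steps. The time course of the ratio S over days T is fitted
with the Hill sigmoid S = S_max·T^h/(k½^h + T^h): S_max is the recovery
plateau, h the recovery rate, and k½ the days to half-maximal recovery.
The fit uses bounded Levenberg–Marquardt with scale-aware initialization
(S_max = max S, h = 1, k½ = median T) and bounds S_max ∈ (0, 2],
h ∈ (0, 10], k½ ∈ (0, 10·max T]; the bounds keep the optimizer away
from degenerate plateaus while comfortably containing physiological
values. R² is reported as 1 − SS_res/SS_tot.

Fisher's exact test (two-sided, probability-mass rule) covers the one
categorical comparison the pipeline needs — proportions of successful
preparations between groups.

## What the generators emulate — and what they do not

The synthetic generators define the study conditions under which the
pipeline is validated:

* `generate_fictive_recording()` builds root traces as white-noise
  carriers multiplied by raised-cosine-plateau burst envelopes (10%
  ramps), in strict flexor/extensor antiphase at 1.2 Hz with a 60%
  extensor fraction, plus additive Gaussian noise. The raised cosine
  gives unambiguous ground-truth onsets while still exercising the
  hysteresis detector's edge behaviour. Spike phases are von Mises
  (sampled with the Best–Fisher rejection algorithm); synaptic events
  are an inhomogeneous Poisson process gated by the flexor/extensor
  phase. Each signal draws from an independent substream of the master
  seed, so adding a spike train never changes the root traces.
* `generate_kinematic_trial()` drives a hip-fixed two-link chain (femur,
  tibia, plus foot) with per-joint waveforms whose slopes vanish at the
  stance/swing transitions, so the toe's horizontal extrema fall exactly
  on the programmed transitions — this is what makes "stance onsets
  within ±1 frame" a well-defined test. Defaults: mouse-scale segments
  (1.6/1.8/0.9 cm), 2.5 steps/s, 60% stance, 250 frames/s.
* `generate_recovery_series()` adds Gaussian noise to a Hill curve and
  clips at zero.

Real recordings differ in ways the generators deliberately ignore:
drifting cycle periods, deleted or deformed bursts, synchronous
(non-alternating) episodes, correlated noise, electrode artifacts,
marker occlusion and skin slip beyond the knee, and compliance of the
treadmill task. Passing the ground-truth tests therefore demonstrates
correctness of the computations under the stated statistical structure,
not robustness to every pathology of real data; the outlier flags,
discard counters, and format validations are the first line of defence
for the latter.

The root-noise level has no published reference statistics; the default
(noise_sd = 0.05 of envelope amplitude) was chosen once as a level at
which burst detection is non-trivial but unambiguous, and is not tuned
thereafter.

## Numerical choices and degenerate inputs

* Half-open intervals everywhere; ties at 0.5 classify as flexor.
* The moving average uses shrinking windows at trace edges (no padding
  artifacts); envelopes keep the input's length and sampling.
* Knee reconstruction clamps the tangent case (|hip − ankle| within
  1 nm of femur + tibia) to the chord solution rather than failing on
  roundoff.
* A flat envelope yields an empty burst list, a flat toe trace zero
  steps, an all-equal-phase sample r = 1 exactly, and an empty phase
  sample an error — degenerate inputs fail loudly or return the exact
  limit, never NaN.
* Seeds are plain 32-bit integers; every seeded routine restores the
  caller's RNG state.

## Problem sizes used in validation

The test-suite simulations use 10–100 cycles of fictive data at 10 kHz,
6–8 step cycles at 250 frames/s, 100 replicate Hill fits at 20 time
points, and 1000-replicate Monte-Carlo checks of the rhythmicity rule's
5% false-positive rate — sizes chosen so each statistical property is
resolvable with comfortable margins.

## Known limitations

* No binary electrophysiology or tracking formats (ABF, Vicon,
  TreadScan): CSV is the interchange format.
* Multi-holding-potential reversal analysis of synaptic currents is
  represented only as input metadata; the detector handles one polarity
  per pass.
* Kinematics are strictly 2-D sagittal; out-of-plane limb motion biases
  the reconstructed knee.
* The rhythmicity rule tests non-uniformity against a unimodal
  alternative; strongly bimodal firing can be called non-rhythmic even
  when patterned.
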