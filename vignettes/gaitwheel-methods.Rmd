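---
title: "Reconstructing and classifying mouse gaits from a force-sensing wheel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and classifying mouse gaits from a force-sensing wheel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwheel)
```

## The instrument and the problem

A saucer-style exercise wheel carries 16 running pads, in 4 groups of 4
separated by support struts, each pad with a magnet on its underside. Nine
Hall sensors in the base sample pad deflection -- and hence vertical ground
reaction force (GRF) -- at 3 kHz in parallel. Because the pad under a foot
rides across the sensor array during a stance, no single channel sees a
whole contact; the single-limb force trace is reconstructed by
*max-concatenation*: at each time point the largest calibrated sensor force
is kept. The wheel's support struts carry no magnet, so the central sensor's
voltage dips four times per revolution, which yields the wheel speed as
`rps = f / (4 s)`, with `f` the sample rate and `s` the samples between
consecutive strut minima.

From the reconstructed trace the package derives stride kinematics (stride
frequency, stance period, duty factor, peak force) and a continuous gait
classification, the stride-signal symmetry score **3S**, which separates
symmetric (trot-like) from asymmetric (gallop/half-bound-like) gaits
without video.

Everything is validated end to end against a physics-based simulator of the
same wheel, so every stage can be tested against known ground truth.

## The virtual wheel and mouse

`generate_trial()` rotates a virtual wheel under a virtual mouse:

* **Limb forces.** Each limb's vertical GRF is a half sine over its stance
  window, placed by Hildebrand footfall timings (per-limb onset phase and
  stance fraction). The peak is set by impulse balance,
  `F_peak = pi * beta * m * g / (4 * DF)`, where `beta` is the weight share
  of the limb's girdle (fore:hind 0.51:0.49 for mice by default, mass 34 g),
  so each pair's stride-averaged force equals its share of body weight.
* **Foot placement.** A foot lands on the pad under its station angle at
  contact onset and rides that pad across the array. Fore feet strike near
  the low-index end of the array and hind feet near the high-index end, so
  stance peaks can be attributed to a girdle from the sensor that read
  them. Two feet landing on one pad (the hind pair in a half-bound) sum
  their forces; feet on different pads compete through the maximum.
* **Sensor response.** The sensor under a pad reads
  `baseline + gain * force` plus Gaussian noise with `3 sigma = 0.04 V`
  (the instrument's stated noise band) and a slow linear drift
  (0.63 mV/h). Voltage-force transfer is linear: the instrument is
  calibrated in its linear regime, so the simulator works there too rather
  than modelling the underlying magnet law. A strut gap passing over a
  sensor dips its voltage by 0.5 V; the dip is masked smoothly when the
  pad read by that sensor carries force, since a nearby loaded magnet
  dominates the sensor -- without this, a stance would black out whenever
  its pad crossed a strut.
* **Foot-position falloff.** Off-centre contacts reading low (the measured
  centre-vs-edge falloff) is *not* modelled: max-concatenation suppresses
  edge contacts in large datasets, and the calibration is defined for
  centred loads.

### Canonical gaits

`canonical_gait()` provides idealised timings: trot (diagonal pairs
synchronous, half a stride apart), half-bound (hind pair synchronous, fore
contacts at 0.45 and 0.70 of the stride), gallop (hind pair split by 0.18
strides), and creep (all four contacts spread so diagonal and girdle-pair
differences are similar). The half-bound's fore phases are chosen so that at
running duty factors (below about 0.30) every stance clears the next hind
contact; overlapping contacts are physically realistic but are exactly the
traces the original impulse analysis excluded, because max-concatenation
masks the overlapped portion.

The cohort generator couples stride parameters to speed: stride frequency
`4.2 + 4 v` Hz (matching the observed 5.3 Hz at 0.31 m/s to 8.3 Hz at
1.0 m/s), trot duty factor `0.64 - 0.36 v` (0.53 down to 0.28 over the same
range), and a lower aerial-phase rule `0.38 - 0.16 v` for asymmetric gaits.
Creeps run slower and more grounded. These rules are fixed properties of
the study conditions, not tuning knobs.

### What the simulator does not emulate

Pad vibration ringing, wheel inertia and propulsion dynamics, tangential
forces, within-trial gait switching, and foot-position falloff are not
modelled. Passing tests therefore demonstrate that the *algorithms* recover
what the instrument can physically encode; they do not certify performance
on animal data, where stance-edge sensitivity and irregular gaits add
error sources the original study quantified against high-speed video.

## Reconstruction choices

* **Calibration** (`fit_calibration`): per-sensor least squares of mean
  voltage against applied force, masses spanning 1-41 g. The simulated
  calibration protocol averages only samples with a magnet pad over the
  sensor; including strut-gap dips would attenuate the recovered slope by
  the dip duty cycle (about 8%).
* **Activity trigger** (`detect_activity`): the central channel departing
  0.2 V from a rolling 1-s median opens an interval; intervals close after
  1 s of quiet and are tiled into 5-s blocks, as the instrument saves them.
* **Speed** (`estimate_speed`): strut minima are local minima 0.1 V below
  the channel median with a minimum separation of `f / (4 rps_max)`
  samples. Intervals far from the running median spacing (outside 0.6-1.6
  times) are discarded as missed or spurious minima -- a missed minimum
  would halve the apparent speed.
* **Negative calibrated forces** are clipped to zero before
  max-concatenation: unloaded pads read baseline noise and strut dips.
* **Smoothing** (`smooth_trace`): a cubic interpolant through knots on a
  uniform grid (about 375 per second) plus the sensor-handoff junctions.
  Knot values take the local mean within half a knot pitch, which removes
  the read noise an interpolant would otherwise thread through, and a
  shape-preserving (monotone Hermite) cubic is used between knots so
  stance-onset corners do not ring. Endpoints are preserved exactly.
* **Stances** (`segment_stances`): contiguous regions above 5% of the
  window peak. Regions holding several prominent peaks are split at
  troughs below 30% of the lower adjacent peak (two contacts bridged by
  noise or a brief overlap); regions whose troughs stay shallow are kept
  whole and flagged multi-peak, and excluded from single-leg statistics --
  the instrument's single-peak rule. Each stance's edges are then refined
  against 5% of its *own* peak, since the window-wide threshold over-trims
  contacts weaker than the tallest one. Stance periods remain slightly
  underestimated (the threshold cuts the half-sine tails), reproducing the
  instrument's known low-speed bias.

## The selective two-peak filter

`two_peak_filter()` implements the very selective band-pass used to extract
the periodic gait signal: keep the two largest non-DC FFT magnitude peaks
(single bins, plus their conjugate partners about half the sample rate),
zero the rest, rescale the kept non-DC coefficients by one common factor so
total signal energy is conserved (Parseval), and invert. Ties go to the
lower frequency. DC is retained unscaled so the mean force stays
meaningful; `zero_dc = TRUE` gives the strict alternative, conserving
energy without the mean. Bin-width leakage for short windows is the main
fidelity limit: a "peak" here is one bin, so off-bin tones spread energy
into neighbours that the filter discards.

## Stride landmarks and the 3S score

Peaks of the splined trace (above 10% of the global maximum, with a minimum
topographic prominence of 10% of the maximum, merged within 15 ms, and
refined by a parabolic fit) are the repeating features. The number of peaks
per stride `P` is the dominant repeat of the inter-peak interval and
peak-height pattern: the smallest lag whose mean-square self-mismatch is
indistinguishable from the best lag. A near-perfectly even train (by
interquartile spread, robust to a stray peak) defaults to `P = 2` -- a
square trot has two indistinguishable contacts per stride. Stride
boundaries fall on every `P`-th peak, anchored at the tallest; the filtered
trace supplies the periodicity check.

`compute_3s()` differences the inter-peak intervals twice and compares the
second difference `u` against a copy of itself circularly shifted by
`round(P / 2)`:

```
3S = MSE(u, shift(u)) / (4 * mean(u^2)),  clipped to [0, 1].
```

A trot-like alternation makes `u` perfectly antisymmetric under the
half-period shift (the shifted copy is its negation), so the normalised MSE
is exactly 1. A skewed short-short-long half-bound pattern scores lower --
any zero-mean period-3 pattern scores exactly 3/4 under this normalisation.
Peak trains whose second difference is small relative to the mean interval
(root-mean-square below 10% of the mean interval) score 1 by convention:
measured peak times always jitter, and the normalised MSE of pure jitter is
about 0.5, which would otherwise invert the ordering for perfectly regular
trots. The score is invariant to time translation and positive rescaling.

Two consequences are worth knowing. First, an ideal bound (hind pair and
fore pair each synchronous, evenly spaced) produces an even two-peak train
and scores 1, in the same band as trotting -- a known property of the
approach, since such gaits are not observed in laboratory mice. Second,
because the score is normalised, its scale is not the original
instrument's: the published cut-off of 0.17 on that scale is not portable,
and `calibrate_threshold()` must be used to re-derive the operating point
on this scale (the trot/half-bound crossing lands near 0.87 here). The
calibration sweeps all midpoints between consecutive sorted unique scores,
computes the proportion of symmetric gaits called symmetric and of
asymmetric gaits called asymmetric, and returns their crossing; it is a
rank statistic, invariant to any strictly monotone transform of the scores.

## Numerical and degenerate-input conventions

* Phases are stride fractions in `[0, 1)`, anchored at first hind contact;
  anchoring never affects pairwise differences. Circular distances fold at
  half a stride.
* The creep rule ("diagonal and girdle-pair timing differences similar")
  uses a tolerance of 8% of the stride period; wider tolerances start
  absorbing realistic gallops, whose diagonal and girdle differences are
  genuinely close.
* The gallop/half-bound boundary is the hind-pair synchrony bound of
  0.025 s in absolute time, so at high stride frequencies (short strides) a
  moderately split hind pair is classified half-bound -- a property of the
  rule, not of the implementation.
* All-zero spectral input returns the input unchanged with scale 1; a flat
  spectrum makes the dominant frequencies undecidable and errors.
* Blocks of three strides whose wheel speed ranges more than 1
  revolution/s (0.25 m/s) are discarded before kinematics, excluding
  accelerating or decelerating strides.
* Simulation sizes in the tests and the acceptance script (2-3 s trials,
  cohorts of 60-200, five impulse trials) are chosen so each estimate's
  sampling error sits well below the tolerance it is tested against.

## Known limitations

* Max-concatenation caps overlapping contacts on different pads at the
  larger force; impulses measured across overlaps are biased low. The
  impulse-ratio estimator therefore expects half-bound traces at running
  duty factors, mirroring the original analysis's restriction to traces
  with distinguishable fore and hind signals, and integrates the raw
  (unsmoothed) trace, whose stance edges are sharp.
* Creeping gaits at high duty factor rarely drop near zero force; their
  stances merge and their peak structure is weak, so creep kinematics and
  3S values are unstable. The original study classified creeps from video
  for the same reason.
* Rotary versus transverse gallops, and lead-leg identity, are not
  distinguishable from the trace at all.
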