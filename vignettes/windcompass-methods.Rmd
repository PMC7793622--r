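---
title: "Models and methods behind windcompass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind windcompass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(windcompass)
```

windcompass simulates and analyzes three kinds of data from experiments on
directional airflow encoding in insect central-complex (CX) columnar
neurons: whole-cell membrane-voltage recordings under multisensory
stimulation, closed-loop tethered-flight behavior with open-loop airflow
perturbations, and two-channel calcium imaging of upstream inputs. Every
analysis stage can therefore be validated against synthetic ground truth
before it touches real recordings. This vignette documents the generative
models, the analysis conventions, and the design choices that were
genuinely open, together with what the synthetic data does and does not
emulate.

All directions are fly-centered degrees on (-180, 180]: 0 front, +90
ipsilateral to the recorded neuron, 180 rear, -90 contralateral.

## The electrophysiology generator

A survey trial lasts 12 s: 4 s pre-stimulus baseline, 4 s stimulus, 4 s
post-stimulus, sampled at 10 kHz. The first second of baseline carries a
500 ms, -2 pA current injection used to track input resistance. Sessions
are block-pseudorandom: each (direction, condition) pair appears exactly
once per block, so the standard survey of 4 directions x 5 cue conditions
x 4 repetitions is 80 trials, and the 8-direction airflow-only design is
40. Inter-trial interval defaults to 9 s.

`neuron_model()` is phenomenological, not conductance-based. Its
components:

* **Baseline state.** Resting potential `v_rest` with an optional pure
  sinusoid (`osc_freq`, `osc_amp`) and white Gaussian noise
  (`noise_sd`, per 10 kHz sample). Recorded CX cell types span resting
  potentials of roughly -40 to -18 mV, input resistances of 1.5-10 GOhm,
  and oscillation frequencies of 2-4 Hz where rhythmic; defaults sit in
  these ranges. The oscillation phase is randomized per trial — baseline
  rhythms are not stimulus-locked — which also keeps the test-pulse
  resistance estimate unbiased across trials.
* **Directional tuning.** A circular-Gaussian (von-Mises-shaped) bump
  with peak 1 at `pref_dir`, parameterized by its half-width at
  half-maximum (`tuning_width`, default 60 degrees). An `inhib` floor
  (default 0.25) shifts the profile down and rescales it so the
  anti-preferred direction drives a *negative* rate: these neurons show
  active inhibition for contralateral airflow, and the firing rate is
  floored at zero while the subthreshold voltage hyperpolarizes
  (`vm_gain` mV per spikes/s of drive).
* **Modality combination.** Per-modality amplitudes `a_air` and
  `a_stripe` (spikes/s at the preferred direction), combined according to
  `integration_mode`: summation adds the two tuned drives;
  airflow-dominant and stripe-dominant zero the non-dominant term when
  both cues are present. Odor multiplies the airflow term by
  `a_odor_gain` (default 0.7, olfactory suppression). The stripe drive
  has its own preferred direction `pref_dir_stripe`, defaulting to
  `pref_dir`; visual and airflow preferences need not coincide, and the
  integration-recovery analyses below use orthogonal preferences so that
  the two unimodal timecourses are distinguishable.
* **Temporal profile.** Tonic (sustained) or transient (exponential
  decay, constant `tau`) drive over the stimulus window.
* **Spiking.** Spike times are drawn from the drive-plus-baseline rate by
  inhomogeneous-Poisson thinning, then thinned again by an absolute
  refractory period (2.5 ms default) so that no two ground-truth spikes
  merge into a single threshold excursion. Spikes are rendered as 2 ms
  triangular depolarizations of height `spike_amp` (40 mV), which a
  40 Hz high-pass filter separates cleanly from the slow components.
* **Test pulse.** The pulse deflects the trace by `current x r_in`
  (pA x GOhm = mV) with exponential edges at the membrane time constant
  `tau_m` (20 ms).

Everything is deterministic given (model, trial, seed); `simulate_session()`
derives one sub-seed per trial.

## Electrophysiology analysis conventions

* **Spike detection** high-passes the raw trace with a second-order
  Butterworth filter (40 Hz cutoff) applied forward-backward (zero phase,
  so detected times are not shifted), then counts upward threshold
  crossings — one spike per suprathreshold excursion. The threshold is
  cell-specific in practice; the default is 5x the median absolute
  deviation of the filtered trace, which self-scales across noise levels
  and is overridable per recording.
* **PSTHs** convolve binned spike trains (1 kHz grid by default) with a
  unit-area 1 s Hanning window and average across trials. The returned
  series extends half a kernel beyond the trial so that no smoothed mass
  is truncated; the integral of the PSTH then equals the mean spike count
  to numerical precision.
* **Windowed responses** are the mean of the response window minus the
  mean of the baseline window; both are 1 s long, ending 500 ms before
  and starting 500 ms after stimulus onset respectively.
* **Input resistance** divides the pulse's steady-state deflection (mean
  over its second half) by the injected current. The defining comparison
  is against the pre-pulse level, but the default pulse begins at trial
  onset, so the reference is a same-length window starting 100 ms after
  pulse offset; with a 20 ms membrane time constant the residual decay
  there is negligible.
* **Baseline profile.** Resting potential is the mode of the baseline
  voltage density; distribution width is the 5th-95th percentile range
  (rhythmic cells are broader); the oscillation frequency is the dominant
  Welch-periodogram peak (2 s Hann segments, 50% overlap, trace decimated
  to 500 Hz) in a 1-10 Hz band, reported only if it exceeds 4x the median
  in-band power. The observed rhythms sit at 2-4 Hz; the post-pulse
  baseline segment (about 3.25 s) spans at least two periods of the 1 Hz
  band edge, which is the resolution floor for this estimate.
* **Strongest-direction response** averages signed per-trial responses
  within direction, picks the direction with the largest absolute mean,
  and reports that absolute mean — so strong inhibition can define a
  cell's best direction. (Averaging signed responses first, rather than
  rectifying per trial, follows the per-cell mean-response convention.)

## Multisensory integration metrics

`summation_points()` compares, per direction, the mean multisensory
response with the sum of the unimodal means (and the trimodal variant
against stripe + odorized airflow). `similarity_coefficients()`
concatenates per-direction mean PSTHs — baseline-subtracted, truncated to
the stimulus-response and offset periods (seconds 4-12) — in the fixed
order (-90, 0, 90, 180) and computes Pearson correlations of the
multisensory timecourse with each unimodal timecourse, giving the pair
(rho_a, rho_s). Pearson is used because the comparison is a point-by-point
linear correlation of rate timecourses. Baseline-subtracted input is the
default (the raw variant is available by passing `baseline_window =
NULL`). A zero-variance concatenated series yields an explicit degenerate
flag with `NA` coefficients, never a silent zero. The coefficients are
invariant to the direction ordering (applied to all conditions alike) and
to positive rescaling of the multisensory series.

## Tuning statistics

`mean_vector()` turns each per-direction mean response into a vector at
the stimulus direction with magnitude equal to the (signed) response and
reports the resultant. Negative responses are kept signed by default, so
inhibition at one direction pushes the resultant away from it; a rectified
variant exists but is non-default. The resultant length is normalized by
the sum of absolute responses, placing it in [0, 1]; the normalization is
a package choice — only the angle is typically compared across cells.
An all-zero curve gives an undefined-angle flag.

`dynamics()` computes the cumulative normalized response over the 4 s
stimulus and the time at which it first crosses 0.5 (linear interpolation
between samples): near 2 s for sustained responses, early for transient
ones. Cells whose integrated response is not positive (inhibited cells)
get an undefined flag rather than a fabricated time.

## The closed-loop arena simulator

The arena runs at 50 Hz. Each sample, the difference in wingbeat angles
(dWBA, positive = rightward) is multiplied by the static gain 0.04 and
applied as degrees of source rotation, clamped at the motor maximum of
144 degrees/s (2.88 degrees per sample). The gain's time base is not
fully pinned down by the hardware description; this package defines it
per control sample, matching the 50 Hz software loop, and notes that only
the mapping from agent parameters to realistic dWBA magnitudes depends on
this choice. The motor cap applies in closed loop as well as during
slips, because the same motor drives both.

Sessions consist of 60 trials of 20 s (20 min), each beginning with one
of six open-loop perturbations presented ten times each in pseudorandom
order: long (2 s) and short airflow pauses, and short (5-sample, 14.4
degree) or long (22-sample, 63.36 degree) slips of the source to either
side, driven at the motor maximum. The nominal short-pause duration of
150 ms is rounded to 8 samples (160 ms) at the 50 Hz loop; a 14.44-degree
figure sometimes quoted for the short slip is treated as a rounding
inconsistency, since 144 x 5 / 50 = 14.4. Perturbation onsets sit 1 s
into each trial so every trial carries a complete 1 s pre-perturbation
analysis window.

The fly agent is a phenomenological controller, not a model of fly
sensorimotor physiology: dWBA = k x (wrapped error between the preferred
flow-relative orientation, 180 degrees downwind by default, and the
latency-delayed orientation) + Gaussian motor noise. While the airflow is
off the agent cannot sense flow and instead applies a fixed dWBA bias
toward the source's last bearing, reproducing the brief toward-source
turns tethered flies make at flow-off. There is no aerodynamics, vision,
or wing kinematics.

Behavior records store dWBA, integrated virtual orientation (wrapped to
(-180, 180]), airflow state and trial labels; the orientation series is
exactly reconstructable from dWBA plus the schedule, and the text reader
validates this invariant on load.

## Behavioral metrics

Fixation metrics treat each orientation sample as a unit vector: the mean
orientation is the resultant angle, fixation strength its length (1 =
perfect fixation; 0 in the uniform limit), and the toward fraction is the
share of samples in the half-open quadrant [-45, +45) around the source
(half-open to avoid double counting; immaterial for continuous data).

Perturbation responses use a 6 s window (1 s pre to 5 s post onset, 301
samples). Slip responses integrate dWBA over the 5 s after onset;
windows that would extend past the session are dropped and counted.
The correction fraction divides the mean integrated response by the
negative signed slip displacement, after converting the dWBA integral
into its equivalent orientation change through the loop (multiplying by
gain x rate) so that numerator and denominator share degree units and a
fraction of 1 means the turning literally undid the slip. Two caveats are
documented rather than hidden: the raw-units variant (`convert = FALSE`)
reproduces the mixed-units ratio as published, and steering effort
exerted *during* the open-loop slip is part of the integral even though
the motor ignores it, so an ideal closed-loop corrector measures slightly
above 1. With constant slip magnitude within a type, the ratio-of-means
and mean-of-ratios formulations coincide up to trial weighting; the
per-trial ratio mean is what `correction_fraction()` returns.

Pause responses flip the sign of dWBA sample-by-sample so that turns
toward the source are positive (the toward sign is -sign(orientation)),
giving a direction-invariant timecourse; long-pause responses are
additionally integrated over the 2 s pause. Slip-response histograms use
20-degree bins centered on multiples of the width, collapse across slip
direction by sign-flipping leftward-slip responses, and normalize to
probabilities.

## Imaging generator and ratiometric correction

An imaging trial is 5 s pre, 10 s airflow, 10 s airflow + odor, 10 s
airflow, 12 s post, at 5 frames/s. The green (activity) channel is
baseline x (1 + tuned response) x a(t) + noise and the red (structural)
channel is baseline x a(t) + noise, where a(t) is a smooth low-frequency
multiplicative artifact shared by both channels (Gaussian noise smoothed
with a 2 s kernel, scaled by `artifact_amp`), emulating brain-movement
fluctuations in the imaging plane. The response uses the same tuning
family as the electrophysiology generator with first-order indicator
kinetics; `sign_invert` produces the sign-inverted tuning of the
LAL-to-noduli input neurons, and odor leaves the response unchanged by
default. Pixel-level synthesis, motion correction and ROI segmentation
are out of scope — the pipeline starts from motion-corrected ROI traces.

dF/F is computed per channel against the mean of the first 5 s of the
trial, and the corrected signal is dF/F(green) - dF/F(red). Because the
artifact is multiplicative and shared, the subtraction cancels it: the
residual scales with the photon noise, not the artifact amplitude. No
detrending beyond the channel subtraction is applied.

## Statistics

Paired comparisons use the Wilcoxon signed-rank test, unpaired the
Mann-Whitney U, distributions the two-sample Kolmogorov-Smirnov, with
Bonferroni correction across comparison families. Tests are two-sided by
default and ties are mid-ranked. Small samples use exact null
distributions (signed-rank up to 12 non-zero differences; rank-sum when
the smaller group is at most 8 and the total at most 16), larger ones the
normal approximation with continuity and tie corrections; the exact and
approximate branches agree to about 0.01 at the boundary. All-zero
difference sets are reported as degenerate rather than given a p value.

## What the synthetic data shows — and what it cannot

Passing tests demonstrate that every analysis stage recovers the known
parameters of these generative models under realistic noise: preferred
directions within a few degrees from 8-direction sessions, spike trains
at better than 99% recall and precision, integration modes from the
(rho_a, rho_s) plane, exact closed-loop bookkeeping, chance-level
statistics for non-orienting flies, and artifact-free corrected dF/F.
They cannot certify behavior on real recordings, which contain features
the generators deliberately omit: non-stationary baselines and cell
health drift, spike-shape variability and bursting, correlated (non-white)
membrane noise, behavioral state changes, non-multiplicative imaging
artifacts, and genuine fly sensorimotor dynamics. The generators'
defaults are the study's stated session designs and parameter ranges;
where no value is stated (noise levels, agent gains, response
amplitudes), values were chosen once to sit in the plausible middle of
each regime and are documented at the parameter definitions.

Problem sizes used by the test suite and the acceptance script — e.g. 20
seeds for direction recovery, 50 per integration mode, 100 for detection
fidelity, 10,000 null simulations for test calibration, 60,000-sample
orientation nulls — balance statistical resolution against a suite that
runs in a couple of minutes on one core.
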