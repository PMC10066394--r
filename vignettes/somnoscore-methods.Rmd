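---
title: "Methods: simulation, featurization and automated scoring of rodent polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, featurization and automated scoring of rodent polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnoscore)
```

## What the package models

Rodent sleep studies score telemetric EEG/EMG recordings into three
vigilance states — wake, NREM sleep and REM sleep — on a fixed 10-s epoch
grid, and then analyze the resulting hypnogram: how long each state lasts,
how it fragments into bouts, when sleep first appears after an
intervention, how often states transition, and how EEG spectral power
(particularly NREM delta, the standard proxy for sleep depth) responds to
treatment. somnoscore implements that entire desk-side pipeline: a
generative simulator of labeled telemetry, the DFT featurization of
epochs, a neural-network scorer, and the architecture/spectral analytics.

All timing is expressed in zeitgeber time (ZT): hours since lights-on,
with the light (rest) phase `[0, 12)` and dark (active) phase `[12, 24)`
under the default 12 h:12 h schedule. Half-open intervals and 0-based
epoch indices are used everywhere.

## The synthetic telemetry generator

No public recordings accompany the study design this pipeline serves, so
the generator is a first-class, tested component: it provides labeled
inputs with the statistical structure the downstream stages assume.

**State switching.** The hypnogram is a first-order Markov chain on the
epoch grid with separate row-stochastic transition matrices for the light
and dark phase. The defaults are free parameters of this package, not
measured values; they were chosen once so that

* stationary occupancies approximate typical rat polysomnography
  (light: ~55% NREM, ~10% REM, ~35% wake; dark: ~30%, ~5%, ~65%), and
* mean dwell times are minutes-scale; for a stay-probability `p` the
  dwell-time law is geometric with mean `1/(1 - p)` epochs (about 2 min
  wake and 3 min NREM in the light phase, ~1.2 min REM), and
* REM is entered only from NREM (`WAKE -> REM = 0`), the physiological
  route in rats; both matrices are overridable.

**Signals.** Each epoch's EEG is band-limited Gaussian noise: white noise
is passed per band through an ideal (FFT brick-wall) filter over the five
classical bands — delta 0.5–4 Hz, theta 4–8, alpha 8–12, sigma 12–16,
beta 16–20 — and the components are weighted by the state's band-weight
fractions, then scaled so the epoch RMS equals the state's amplitude.
An ideal filter was chosen over an IIR design deliberately: it keeps the
in-band spectrum flat and smooth, puts exactly the intended power fraction
in each band (a Butterworth filter leaks several percent across band
edges), and makes the spectral-fidelity property below exact in
expectation. EMG is white noise at the state's RMS amplitude with the
atonia ordering REM < NREM < wake; activity is a per-epoch Poisson count
emitted only in wake epochs with phase-specific rates; core temperature
follows a cosinor (mesor 37.3 °C, amplitude 0.5 °C, acrophase ZT 18)
plus Gaussian jitter. The default state phenomenology (wake low-amplitude
high-frequency EEG + high EMG; NREM high-amplitude delta-dominant EEG +
low EMG; REM low-amplitude theta-dominant EEG + near-zero EMG) follows
the standard scoring descriptions; amplitude values (40/120/50 µV EEG,
80/30/8 µV EMG) are plausibility choices, clearly labeled free
parameters.

**Treatment effects** are directional knobs emulating an acute hypnotic
drug given at a phase boundary: a multiplier on wake-to-sleep transition
probabilities (rows renormalized), a multiplier on the delta band weight
(renormalized through the amplitude scaling), an activity-rate multiplier
and a temperature offset, all active only for epochs inside a ZT window.
They are not calibrated to any particular compound; the pipeline's job is
to recover their direction, not their magnitude.

**Determinism.** One integer seed drives a recording; per-channel
sub-streams are derived from it, so identical (parameters, seed) pairs
are bit-identical. The sampling rate defaults to 250 Hz (configurable;
anything ≥ 40 Hz supports the 20 Hz analysis ceiling).

## Featurization

Each 10-s epoch is transformed with a single DFT (rectangular window, no
detrending — 0.1 Hz resolution, which tiles cleanly into 0.5-Hz
channels). Power is summed into 40 half-open channels of equal width
covering 0–20 Hz, and each channel is divided by the total 0–20 Hz power.
Total power thus acts as the normalizer of the 40 channels rather than as
a separate feature — the only arithmetic consistent with a 42-feature
epoch once average EMG (epoch RMS) and the activity count are appended.
The DC bin is excluded from channel 0 so a constant offset cannot
dominate the lowest channel. An epoch with exactly zero EEG power yields
an all-zero channel vector with a warning; NaN samples are an error
naming the epoch.

A moving window of five consecutive epochs (stride 1) concatenates five
42-feature vectors into a 210-feature sample, so `n` epochs give `n - 4`
samples. Training labels use the most common state among the five epochs.
With three classes a 2-2-1 tie is possible; it resolves to the center
epoch's state, or — when the center state is not one of the tied
leaders — to the tied state appearing earliest in the window. Epoch grids
are anchored at the recording start, and recordings are assumed to start
on an integer ZT second.

## The classifier

The scorer is a fully connected network: 210 inputs, one hidden layer of
512 rectified-linear units, 3 softmax outputs. Labeled samples are
partitioned 64% / 16% / 20% into training, validation and test sets,
stratified by class; the validation and test totals are fixed globally
(nearest-integer) and apportioned across classes by largest remainder,
with every remaining sample going to training, so 1000 samples always
split 640/160/200. Because REM is rare, the training split (only) is
balanced by oversampling minority classes with replacement to the
majority count.

Optimization details are this package's choices, exposed in
`mlp_config()`: cross-entropy loss, Adam (learning rate 1e-3), minibatch
256, features z-scored with training-split statistics (necessary given
the mixed units: power fractions, microvolts, counts), one validation
check per pass with patience 10 and a 60-pass cap, best-checkpoint
weights retained. Initialization and shuffling are seeded; training is
exactly reproducible. Prediction takes the softmax argmax (exact ties to
the lowest class index); per-epoch hypnograms assign each epoch its
centered window's label, with the first and last two epochs inheriting
the nearest window's label.

Evaluation reports accuracy, per-class and macro F1 (`2PR/(P+R)`, 0 when
undefined) and the 3×3 confusion matrix. On ten simulated 24-h recordings
at the defaults the held-out agreement exceeds 95%, the level human
scorers and automated scoring are conventionally expected to reach. That
figure is against *synthetic* truth: the generator's states are cleanly
separated by construction (band weights, EMG tone, activity), with no
artifacts, electrode drift, or ambiguous transitional epochs, so passing
it demonstrates the pipeline's correctness, not expected accuracy on real
rats.

## Hypnogram architecture

A *bout* is any maximal run of one state (minimum one epoch). A
*transition* is scored only when two or more consecutive epochs carry the
new state: a running "scored state" is carried along the run-length
encoding; runs of length ≥ 2 that differ from it score one transition and
update it; single-epoch excursions never score and never update. These
two definitions are deliberately asymmetric — a lone REM epoch is a bout
but not a transition — which is the only reading under which both printed
rules hold simultaneously. Each transition is attributed to the phase of
the first epoch of the new state's run.

Onset latency (NREM or REM) is the time from a phase start (which
coincides with injection time in a dosing experiment) to the first run of
≥ 2 consecutive target-state epochs; absent such a run the value is
flagged missing rather than imputed. Binned summaries (1-h and 6-h)
report per-state minutes, bout counts and mean bout durations; a bout
straddling a bin edge is counted once, at full length, in its starting
bin (its *minutes* still accrue to the bins where the epochs lie, so
per-bin durations always sum exactly to the bin length). Treatment
contrasts are computed per matched bin as percent change
(`100 (T - V)/V`, undefined — never infinite — when the vehicle cell is
zero) and as within-subject absolute differences.

## Spectra

State- and phase-resolved spectra average the 40 normalized channel
powers over qualifying epochs, using whichever hypnogram is under
analysis (truth labels for simulations, predictions for end-to-end runs —
stated per output). Spectra are fractions of total 0–20 Hz power by
default (an absolute-power interpretation is a matter of multiplying back
the stored totals; the published normalization is unstated, and fractions
make arms comparable); band powers sum the bins whose centers fall in the
half-open band. The delta band starts at 0.5 Hz per the methods-grade
definition (a conflicting 0–4 Hz phrasing exists in looser prose; the
0.5 Hz bound is used, and the 0–0.5 Hz residual is reported separately so
the five bands plus residual partition the total mass exactly).
Per-epoch DFT is the only estimator offered — no Welch/multitaper — to
stay faithful to the featurization path, and band powers computed from a
profile agree with band powers computed directly from the raw signal to
1e-9 because both routes share one DFT implementation.

## Numerical and design notes

* Frequency channels and bands are half-open `[lo, hi)`; bin-to-channel
  assignment guards against floating-point edge error with a 1e-9 nudge.
* A 2-2-1 window-label tie with the center epoch outside the tied pair
  falls back to the earliest tied state (deterministic; the center rule
  covers every case the design text specifies).
* Exact softmax ties predict the lowest class index.
* The EDF writer quantizes to 16 bits against each channel's physical
  extremes; round trips are exact to one quantization step. Epoch-level
  channels travel in a TSV sidecar because their 0.1 Hz effective rate
  fits EDF records awkwardly.
* Degenerate inputs fail loudly with classed validation errors:
  non-stochastic matrices, non-epoch-multiple durations, misaligned
  hypnograms, sidecar row-count mismatches, empty test sets.

## Problem sizes used by the checks

The test suite and the reproduction script size their simulations as
follows, chosen once as realistic desk-scale study conditions: ten 24-h
recordings (86,400 epochs, 17,272 held-out windows) for the end-to-end
classification check; 50,000 epochs for the dwell-time law (3-SE
Monte-Carlo band — REM bouts are rare, and this length keeps all three
states well-powered); 1,000 random label sequences (lengths 1–500)
against brute-force bout/transition scanners; one 24-h two-arm virtual
experiment for the treatment-direction check.

## Limitations

The simulator emulates state-dependent spectra, amplitudes, circadian
rhythm and phase-dependent switching, but not artifacts, inter-subject
variability, electrode degradation, scorer disagreement, or ambiguous
transitional epochs; classifier performance on it is an upper bound.
Treatment knobs are directional only. Statistical inference (repeated
measures ANOVA, mixed models, post-hoc tests) is out of scope: the
package produces the tidy per-bin tables such analyses consume.
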