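---
title: "Scoring EEG / eye-movement synchronization with band-power ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring EEG / eye-movement synchronization with band-power ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyesync)
```

## The question the pipeline answers

While a viewer watches an emotional video, do the slow fluctuations of an
eye-movement feature (pupil diameter, fixation displacement, saccade
amplitude) co-move with the spectral composition of a scalp EEG channel?
`eyesync` operationalizes "co-move" as a prediction problem: for one
(eye feature, EEG channel, band) triple, how much of the EEG channel's
relative band-power trajectory can a regression model predict from the
eye feature's relative band-power trajectory on held-out time windows?
The held-out coefficient of determination (R²) is the synchronization
score. Scores are then compared between empathic and non-empathic
viewing conditions, with exclusion rules that discard triples whose
empathic advantage is absent or within noise.

## Feature chain

**Blink removal.** Gaze samples with a non-positive pupil diameter or a
false validity flag are treated as blink-affected. Each blink is padded
by 100 ms on both sides (eyelid occlusion corrupts pupil estimates
before the signal drops out) and pupil diameters and gaze coordinates
are linearly interpolated across the padded span. Sessions that are
more than half blink are rejected. Windows in which more than 20% of
samples were interpolated are flagged and excluded from regression.

**I-VT classification.** Point-to-point gaze velocity above a threshold
(default 30 units/s, the conventional deg/s setting) marks saccade
samples; runs of saccade/non-saccade samples become events. Fixations
shorter than 60 ms squeezed between saccades are absorbed into the
saccade. Events partition the timeline.

**Eye feature series.** Four series at 60 Hz: (1) fixation distance —
the Euclidean distance between consecutive fixation centroids, held
from each fixation's onset (a step series; the sparse event values must
be uniformly sampled before sub-Hz band-pass analysis is meaningful);
(2) saccade amplitude — the point-to-point displacement of each
saccade, emitted during that saccade's samples, zero elsewhere; (3, 4)
left and right pupil diameter, mean-centered per session so band powers
reflect fluctuation structure rather than baseline diameter. A
compatibility flag (`literal_norm`) switches the fixation measure to
the norm-of-coordinates variant; the centroid-to-centroid distance is
the default because that is what a "distance between two fixations"
means geometrically.

**Relative band power.** A window of the signal is mean-removed,
Hann-tapered, and its one-sided periodogram summed into four half-open
bands. EEG uses delta 1–4, theta 4–8, alpha 8–13, beta 13–20 Hz (after
a 1–50 Hz acquisition band-pass); eye features use a compressed sub-Hz
scheme, delta 0.12–0.48, theta 0.48–0.96, alpha 0.96–1.56, beta
1.56–3.6 Hz. Each band's power is divided by the summed power of the
four bands, so the four ratios sum to one. The denominator is the
four-band total (not the full-spectrum total): this makes the ratios a
composition over exactly the range analyzed downstream; a full-spectrum
denominator is available via `band_ratios()` on unnormalized powers.
Windows are 180 s long and slide by 1 s, giving
`floor((duration - 180)/1) + 1` windows; at the native rates an eye
window holds 10,800 samples and an EEG window 90,000 — the two
modalities stay aligned because both grids are indexed by the same
window start times, not by sample counts.

**Why the band-summed periodogram and not filtered variance.** Both
routes estimate the same quantity; the periodogram route needs one
transform per window and assigns every bin to exactly one band
(half-open intervals, so a shared edge like 4 Hz belongs to theta). The
zero-phase band-pass (`bandpass()`) applies the squared magnitude
response of a 4th-order Butterworth in the frequency domain; at a 500 Hz
rate the sub-Hz eye bands put time-domain IIR coefficients far outside
their numerically safe range, while the frequency-domain form is exact
for any band.

## Synchronization scoring

Aligned window pairs (same band, same window start) are split 7:3. The
default split is chronological: windows overlap by 179/180 of their
length, so a random split places near-duplicates of training windows in
the test set and the measured R² reflects memorization rather than
prediction. The random split is retained (`split_mode = "random"`)
because it is what the five-model comparison table assumes, and the
`evaluate_models()` repeats use it; the headline synchronization scores
use the chronological split.

Five regression families are available with fixed, conventional
settings: Bayesian ridge (evidence maximization, 1e-6 gamma
hyperpriors), ordinary least squares, elastic net (penalty weight 1.0,
mixing 0.5 — at these band-ratio scales the penalty shrinks the slope
to zero, and the model predicts the training mean; this is faithful to
the stated settings, not a bug), epsilon-SVR (RBF kernel, C = 1,
epsilon = 0.1, gamma = 1/n_features), and gradient boosting regression
(100 stages, learning rate 0.1, depth 3, squared-error loss). Held-out
MAE, MSE and R² are reported; R² may be negative and is not clipped. A
zero-variance test response makes R² undefined and is flagged. GBR is
the default scoring model; `select_best_model()` picks the top
R²-score with ties broken by lower MSE.

## Condition comparison

Per (feature, channel, band, quadrant), each session contributes one
R² to its condition group. Groups are summarized by mean and sample
standard deviation and compared with a two-tailed Welch t-test (the
unequal-variance form; the condition groups have no reason to share a
variance). Two exclusion rules then apply: a triple is discarded if
(1) the non-empathic mean is at least the empathic mean, or (2) the
`mean ± 1 sd` intervals of the two conditions intersect. The ±1 sd
reading matches how condition means are conventionally plotted with
standard-deviation bars; standard-error intervals are available via
`interval = "se"`. No multiple-testing correction is applied to the
decision; a Benjamini–Hochberg adjusted p-value is reported alongside
for reference. Channels are tagged left/right/midline by 10–20 name
parity (odd/even/z), and pupil-side versus channel-side gives
same/crossed hemisphere tags in the quadrant report.

## The synthetic generator

No public recording of this kind exists, so the package ships a
generator whose sessions carry known ground truth. Its defaults encode
the study conditions: 18 channels at 500 Hz, gaze and pupils at 60 Hz,
eight videos per subject labelled by the two (empathy) × two (valence)
× two (arousal) factorial with one empathic and one non-empathic video
per quadrant, 300 s per video (stimulus durations are not public; 300 s
comfortably exceeds the 180 s window), blinks at 15/min of 200 ms
(typical spontaneous rates), saccades at 2/s with log-normal
amplitudes, and 0.05 mm pupil measurement noise.

**Coupling model.** Each planted coupling realizes a latent source as
band-limited Gaussian noise inside the eye-band edges of its band
(synthesized in the frequency domain, so spectral placement is exact).
The eye side adds the latent into the feature's generative trace with
weight `strength` (for pupils, an additive 0.2 mm-scale component —
large enough to dominate in-band cross-terms with the background,
small enough that the coupled band's ratio stays in its sensitive
range rather than saturating toward 1; for saccade-driven features, a
multiplicative modulation of saccade amplitudes). The EEG side
amplitude-modulates that band's rhythm so that the squared envelope is
linear in the latent's instantaneous power — the exact quantity the
eye side's window band power measures — which is what makes the EEG
band-ratio series track the eye band-ratio series.

**Backgrounds are rhythms, not noise.** Each modality's background is a
mixture of narrowband oscillators (one per band, constant modulus, slow
phase noise — the EEG analogue of an alpha rhythm, the pupil analogue
of slow hippus) plus weak broadband noise. This is deliberate: a purely
stochastic band-limited background contributes window-power sampling
fluctuations of relative size `1/sqrt(bandwidth × window)`, which at a
20 s window in a 0.36 Hz-wide band is ~40% — enough to bury a planted
coupling in band-limited cross-terms. Constant-modulus rhythms keep the
background's window power nearly deterministic, so the ratio trajectory
of a coupled band is governed by the latent. The weak broadband term is
kept on purpose: without it an uncoupled channel's ratio trajectory is
almost exactly constant, the held-out variance of a null regression
degenerates, and null R² values reach three-digit negatives (see
below).

**The nonlinear link.** `link = "monotone_nonlinear"` passes the eye
side through a rescaled cube. The cube is projected back into the
latent's own band before use: cubing a narrowband signal cubes its
amplitude envelope but also dumps roughly three quarters of the power
into the third-harmonic band, which would break the latent's spectral
placement and (more damagingly) turn the windowed power of the cubed
trace into a noisy sixth-moment estimate. The in-band cube keeps the
monotone amplitude distortion — windowed power goes as the cube of the
latent's local power — which is the curvature a gradient-boosted model
exploits and a straight line cannot. The cubed trace carries 1.5 times
the linear link's amplitude so its heavy-tailed power excursions span
the band ratio's sensitive range instead of collapsing into its flat
lower end.

**What the generator does not emulate.** No 1/f spectral shaping, no
volume conduction or channel covariance, no smooth pursuit, no
microsaccades, no stimulus-locked structure. Passing tests demonstrate
that the pipeline recovers plantings of the stated form at realistic
noise levels; they do not certify performance on real recordings.

## Numerical and design choices

- **Windows per session and R² stability.** With a chronological 7:3
  split, the held-out segment must span several window lengths:
  adjacent sliding windows share all but one second of data, so the
  test segment contains roughly `test_span / window_s` independent
  observations. If that ratio is near or below one, the held-out
  variance can be arbitrarily small and R² arbitrarily negative — a
  numerical artifact, not a property of the signals. The simulation
  profile used by the test suite therefore pairs 20 s windows with
  240 s sessions (test span ≈ 3.6 window lengths); the fidelity
  profile's 180 s windows would need ~40-minute sessions for the same
  stability, which is one reason held-out scores at the fidelity
  geometry should be read with caution.
- **Per-session RNG streams.** Every session draws from a stream keyed
  by (seed, subject, video), so cohorts are reproducible regardless of
  generation order, and any single session can be regenerated in
  isolation.
- **Determinism.** The boosted model runs single-threaded with a fixed
  seed; two identical pipeline runs produce byte-identical CSVs.
- **Degenerate inputs.** All-zero windows yield flagged undefined
  ratios; fewer than two fixations yields an all-zero distance series
  with a warning; fewer than ten aligned windows refuses to split;
  groups of one report a mean but no standard deviation, and the
  overlap rule then excludes conservatively.
- **Edges and ties.** Band bins are half-open `[f_lo, f_hi)`;
  model-selection ties break by lower MSE, then by a fixed model-name
  order.

## Known limitations

- The chronological split removes train/test leakage but cannot remove
  the window-overlap autocorrelation *within* each segment; effective
  sample sizes are far smaller than window counts, and p-values from
  the Welch test inherit that optimism.
- Eye and EEG clocks are assumed to start together; no cross-device
  synchronization signal is modelled or corrected.
- The elastic net at its stated penalty is a constant predictor on
  band-ratio data; it is included for completeness of the five-model
  comparison, not as a usable scorer.
- EDF export quantizes to 16 bits over each channel's observed range;
  round-trips are exact only to that quantization.

## A small worked run

```{r, eval = FALSE}
library(eyesync)
library(dplyr)

cfg <- run_config(
  synth = synth_config(
    n_subjects = 3, n_videos = 2, duration_s = 240,
    couplings = coupling_spec("pupil_right", "F3", "delta",
                              strength = 0.95, empathic = TRUE),
    seed = 1),
  window_s = 20,
  features = c("pupil_right", "pupil_left"),
  channels = c("F3", "T5"), bands = "delta")

out <- run_pipeline(cfg, tempfile("eyesync_run"))
out$comparisons |>
  select(eye_feature, channel, band, mean_emp, mean_non,
         p_value, retained)
```

The planted (pupil_right, F3, delta) triple shows a large positive
empathic mean against a negative non-empathic mean; unplanted triples
fail one of the exclusion rules.
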