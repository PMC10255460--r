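# eyesync

Quantifies cross-modal synchronization between scalp EEG and eye
movements recorded while a viewer watches emotional videos, and compares
it between empathic and non-empathic viewing conditions. It is written
for researchers in affective computing and physiological signal
analysis who have (or want to simulate) dual-rate recordings: 18-channel
EEG at 500 Hz (10–20 montage) and a 60 Hz gaze/pupil stream.

## The method

For one eye-movement feature *x* (fixation distance, saccade amplitude,
or left/right pupil diameter) and one EEG channel *y*, both signals are
reduced to **relative band-power ratio series**: a 180 s window slides
in 1 s steps, and within each window

```
ratio_b = P_b / (P_delta + P_theta + P_alpha + P_beta)
```

where `P_b` is the periodogram power in band *b*. EEG uses delta 1–4,
theta 4–8, alpha 8–13, beta 13–20 Hz; eye features use a compressed
sub-Hz scheme (delta 0.12–0.48, theta 0.48–0.96, alpha 0.96–1.56, beta
1.56–3.6 Hz). For each like-named band, a regression `y = f(x)` is fit
on the first 70% of windows and evaluated on the held-out 30%:

```
MAE = (1/m) Σ |h(x_i) − y_i|
MSE = (1/n) Σ (y_i − ŷ_i)²
R²  = 1 − Σ (y_i − ŷ_i)² / Σ (y_i − ȳ)²
```

The held-out R² is the synchronization score for that (feature,
channel, band) triple. Five regression families are available (Bayesian
ridge, linear, elastic net, SVR, gradient boosting); gradient boosting
is the default scorer. Condition-level comparison uses per-session R²
values: Welch's two-tailed t-test per triple and quadrant of the
valence–arousal model, with two exclusion rules — a triple is dropped
if the non-empathic mean exceeds the empathic mean or if the two
`mean ± sd` intervals overlap.

Because no dataset of this kind is publicly deposited, the package
includes a synthetic-data module (`synth_config()`,
`generate_session()`, `generate_cohort()`) that plants band-limited
latent couplings with known strength between chosen eye features and
EEG channels, so the entire pipeline is verifiable against ground
truth. See the methods vignette (`vignettes/eyesync-methods.Rmd`) for
the generative model and every numerical choice.

## Worked example

Plant a coupling between the right pupil and channel F3 in the delta
band, active only in empathic sessions, and run the full pipeline:

```r
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

out <- run_pipeline(cfg, "eyesync_out")
out$comparisons |>
  select(eye_feature, channel, mean_emp, std_emp,
         mean_non, std_non, p_value, retained)
#> # A tibble: 4 × 8
#>   eye_feature channel mean_emp std_emp mean_non std_non p_value retained
#> 1 pupil_left  F3        -2.17    0.487   -0.276   0.441 0.00767 FALSE
#> 2 pupil_left  T5        -0.634   0.609   -0.371   0.114 0.536   FALSE
#> 3 pupil_right F3         0.684   0.183   -0.926   0.244 0.00112 TRUE
#> 4 pupil_right T5        -0.671   0.547   -0.311   0.156 0.374   FALSE

pipeline_report(out)
#> == pleasant-aroused (1 retained) ==
#>   pupil_right  F3  delta  emp 0.684+/-0.183  non -0.926+/-0.244  p=0.00112* [crossed]
```

Reading this: the planted triple is the only one retained — its
empathic-condition synchronization (mean held-out R² = 0.68 across
sessions) clearly exceeds the non-empathic condition, the ±1 sd
intervals are disjoint, and the Welch test gives p = 0.0011. The
uncoupled triples are excluded by the mean rule or the interval-overlap
rule. `[crossed]` tags the right-pupil/left-hemisphere (F3) pairing.

`plot_comparison(out$comparisons)` draws the condition bar chart with
±1 sd error bars; `autoplot()` on a single `fit_sync()` object overlays
predicted and observed band-ratio trajectories.

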