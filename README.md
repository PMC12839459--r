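# neuromotor

Quantitative neurophysiology for spinal-cord-injury research platforms in
non-human primates: analysis of epidural-stimulation (EES) evoked motor
responses, chronic locomotor EMG, and treadmill gait kinematics. The package
is for electrophysiologists and motor-control researchers who record
multichannel intramuscular EMG (4 kHz), stimulus-event tables, and
video-derived joint-angle goniograms, and need the standard assessment chain
as tested, scriptable R functions rather than one-off lab code.

## What it computes

* **EMG conditioning** — zero-phase 50 Hz notch and 20–1000 Hz Butterworth
  band-pass, rectification, linear envelopes
  (`notch_filter()`, `bandpass_filter()`, `rectify()`, `envelope()`).
* **Evoked responses** — stimulus-triggered epochs, five-stimulus averages,
  maximum peak-to-peak amplitude *A*<sub>pp</sub>, onset latency (first
  sustained crossing of 3 baseline SDs, sub-sample interpolated), and the
  response-presence criterion *A*<sub>pp</sub> > 3 × SD(noise window)
  (`extract_epochs()`, `average_epochs()`, `detect_response()`,
  `onset_latency()`).
* **Recruitment and motor threshold** — amplitude versus current over
  1–14 mA sweeps in 0.1 mA steps; threshold = smallest current exceeding
  3 × noise SD with its successor (two-consecutive rule)
  (`recruitment_curve()`, `motor_threshold()`).
* **SSEP P1/N1** — latency and peak-pair amplitude of averaged cortical
  somatosensory evoked potentials (`ssep_features()`).
* **Antagonist coactivation** — the bounded [0, 1] Rudolf-style coefficient
  `Σ min(aᵢ, bᵢ) / Σ max(aᵢ, bᵢ)` on normalized envelopes, plus the
  L-shaped coordination profile (`coactivation_index()`,
  `coordination_profile()`, `coactivation_table()`).
* **Gait kinematics** — autocorrelation step-period estimation, 1.5-step
  analysis windows, range of motion (max − min angle) per window and per
  session (`estimate_step_period()`, `segment_windows()`,
  `summarize_rom()`).
* **Reporting statistics** — mean ± SEM, median [IQR], Shapiro–Wilk,
  paired t tests (`group_summary()`, `paired_comparison()`), and pipeline
  drivers emitting tidy CSV/JSON reports (`run_evoked_pipeline()`,
  `run_gait_pipeline()`).
* **Synthetic recordings with ground truth** — seeded generators for evoked
  sweeps, locomotor antagonist EMG, goniograms and SSEPs
  (`make_evoked_recording()` and friends), so the whole chain is testable
  without animal data.

Functions take data frames (or the light `recording` container) first and
return tibbles; fitted summaries have `tidy()`, `glance()` and `autoplot()`
methods.

## Worked example

```r
library(neuromotor)

# A synthetic recruitment sweep: threshold 3 mA, 1-14 mA in 0.1 mA steps,
# five 2 Hz stimuli per current, 5 % noise, onset latency 4.2 ms.
sweep <- make_evoked_recording(evoked_config(
  onset_latency_ms = 4.2, threshold_ma = 3,
  currents_ma = rep(seq(1, 14, 0.1), each = 5), noise_sd_uv = 30, seed = 1))

curve <- recruitment_curve(sweep$recording, "RF_R")
glance(curve)
#> # A tibble: 1 × 4
#>   channel threshold_ma noise_sd_uv n_currents
#>   <chr>          <dbl>       <dbl>      <int>
#> 1 RF_R               3        29.8        131
```

The estimated motor threshold (3.0 mA) recovers the generator's injected
threshold exactly on the 0.1 mA grid; `autoplot(curve)` draws the
recruitment curve with the 3 × SD criterion line and threshold marker.

```r
out <- run_evoked_pipeline(sweep$recording)
dplyr::filter(out$responses, current_ma == 9)
#> # A tibble: 1 × 8
#>   channel current_ma n_epochs noise_sd_uv amplitude_pp_uv present latency_ms latency_avg_epoch_ms
#>   <chr>        <dbl>    <int>       <dbl>           <dbl> <lgl>        <dbl>                <dbl>
#> 1 RF_R             9        5        10.2            605. TRUE          4.32                 4.13
```

At 9 mA (suprathreshold) the response is present, its five-epoch average
peaks at ~605 µV, and the five-stimulus mean onset latency is 4.32 ms
against the injected 4.2 ms — within the ±0.3 ms the estimator promises at
this noise level.

```r
# Range of motion of a post-injury right-hip goniogram (10.9 deg per cycle)
g <- make_goniogram(gonio_config(rom_deg = 10.9, seed = 1))
summarize_rom(g$goniogram, smooth_frames = 3)
#> <rom_summary> 49 windows of 1.200 s (period 0.800 s)
#>   mean ROM 11.27 deg, median 11.25 deg [IQR 11.10, 11.41]
```

The step period (0.8 s) is recovered from the autocorrelation, the 60 s
trace is tiled into 1.5-step windows, and the mean ROM lands within ~3 % of
the injected value despite 0.5° frame jitter.

## Limitations

The generators emulate the statistical structure the estimators assume
(band-limited noise, phase-locked bursts, logistic recruitment, frame
jitter) but not stimulation artifacts, powerline harmonics, electrode
drift, or marker dropouts; see the methods vignette
(`vignettes/neuromotor-methods.Rmd`) for the full model, calibration
decisions, and known limitations.
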