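---
title: "Methods: evoked responses, coactivation, and gait kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked responses, coactivation, and gait kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromotor)
```

## What the package computes

`neuromotor` implements the quantitative chain used to assess motor function
in non-human-primate spinal-cord-injury platforms that combine epidural
electrical stimulation (EES) with chronic intramuscular EMG and video
kinematics:

* conditioning of raw EMG (50 Hz notch, 20–1000 Hz band-pass, rectification,
  linear envelope), sampled at 4 kHz;
* stimulus-triggered epoching of EES-evoked compound motor responses, with
  onset latency, maximum peak-to-peak amplitude, and a response-presence
  criterion (`A_pp > 3 × SD` of a designated noise window);
* recruitment curves over graded 1–14 mA sweeps in 0.1 mA steps and motor
  threshold estimation;
* P1/N1 latency and amplitude of averaged cortical somatosensory evoked
  potentials (SSEPs; 50–250 sweep averages);
* a bounded [0, 1] antagonist-coactivation ("Rudolf") coefficient and the
  L-shaped coordination profile over locomotor EMG envelopes;
* automatic step-period estimation, 1.5-step analysis windows, per-window
  range of motion (ROM, max − min joint angle) and per-session summaries;
* the reporting statistics: mean ± SEM, median [IQR] with type-7 quartiles,
  Shapiro–Wilk normality, and two-sided paired t tests at α = 0.05.

Raw animal recordings from such platforms are rarely deposited, so the
package ships seeded generators (`make_evoked_recording()`,
`make_locomotor_emg()`, `make_goniogram()`, `make_ssep_recording()`) that
produce recordings with the statistical structure the analysis assumes plus
ground-truth sidecars. Every estimator is validated by parameter recovery
against those sidecars at the physiological operating points (onset
latencies 3–6 ms, thresholds 2.5–4 mA, hindlimb ROM regimes from ~3° after
injury to ~35° under EES).

## Units and conventions

Absolute time is in seconds; epoch-relative time and latencies are in
milliseconds; EMG in µV; joint angles in degrees; currents in mA. All window
selections are half-open `[start, stop)`, so adjacent windows never share a
sample, and slicing `[a,b)` then `[a,c)` equals slicing `[a,c)` directly.
Channels follow a `<MUSCLE>_<SIDE>` naming scheme (`TA_R`, `GM_L`, ...),
which disambiguates the inconsistent muscle abbreviations common in this
literature.

## Filtering

The filter family is a design choice (protocols in this field rarely state
one): a 4th-order Butterworth band-pass (20–1000 Hz) and a 2nd-order IIR
notch (50 Hz, Q = 30), both applied forward–backward. Zero-phase application
matters because onset latency is a first-crossing statistic: a causal filter
would delay every onset by its group delay. Both filters use reflect padding
of three filter lengths so that startup transients never reach the short
(≤ 60 ms) evoked windows. Linearity and the zero-lag property are verified
by tests (relative tolerance 1e-8; cross-correlation peak at lag 0).

## Onset latency

Onset is the first time in the search window (default 1–20 ms
post-stimulus) at which the absolute deviation from the baseline mean
exceeds 3 baseline SDs and stays above it for at least 0.5 ms. This reuses
the same SD family as the presence criterion rather than introducing a
second detector. Two numerical details:

* the crossing time is linearly interpolated between the bracketing
  samples; at 4 kHz this removes a +0.125 ms mean grid bias;
* a degenerate baseline (SD = 0) is flagged with a warning and any
  deviation counts as onset.

The residual positive bias is the time the template needs to climb from
zero to 3 SD of the noise — about 0.13 ms at 5 % noise for a biphasic
response of 3 ms duration — well inside the ±0.3 ms recovery band used in
the tests. Latencies reported per group are the mean of the per-epoch
latencies over five consecutive stimuli (the convention for this assay),
not the latency of the averaged epoch; both are exposed by
`run_evoked_pipeline()`.

## The 3×SD presence criterion and its statistics

`detect_response()` implements the criterion literally: present iff the
maximum peak-to-peak amplitude of the response window exceeds 3 × the
sample SD of the noise window. Two consequences are worth understanding:

* On a **raw, unaveraged** epoch with a wide response window the criterion
  is liberal by construction: the expected range of ~100 band-limited noise
  samples is itself ≈ 4.6 SD, so pure noise is declared "present" almost
  surely. The acceptance suite quantifies this by comparing the package's
  false-positive rate on 1000 pure-noise epochs against a brute-force
  Monte-Carlo of the same rule — they agree, because the rule is the rule.
* The criterion becomes informative on **averaged** traces (the noise range
  shrinks as 1/√n while a real response does not) and on **identified peak
  pairs** rather than window ranges.

Accordingly, for peripheral evoked responses the pipeline applies the
criterion to the five-epoch average with a pre-stimulus noise window
(cortical 0–5 ms windows would overlap a 3–6 ms onset), and for SSEPs the
amplitude entering the criterion is the P1–N1 peak-pair amplitude with the
0–5 ms post-stimulus noise window (cortical components arrive later).

## SSEP P1/N1

Averaged SSEPs are searched (default 10–40 ms) for the adjacent pair of
local extrema with the dominant swing; for physiological SSEPs this is the
first major positive/negative complex. The positive member is P1 and the
negative member N1 — deliberately agnostic to order, since an inverted
montage (or genuinely early negative component, which published cortical
data do show) simply swaps the roles while preserving the amplitude. Before
peak finding the trace is smoothed zero-phase at 150 Hz, matched to the
several-millisecond component width, so that sample-scale ripple on the
average does not masquerade as a component; the noise SD entering the
presence criterion is measured on the unsmoothed average (that is the noise
the response must beat). The smoothing attenuates component amplitude by
≈ 2 %, far below the criterion's margins.

## Recruitment curves and motor threshold

The amplitude at each sweep current is the peak-to-peak of the
pointwise-averaged epochs at that current (stimulus-triggered averaging,
five stimuli per current in the shipped protocol). Averaging before
measuring is essential: the mean of per-epoch peak-to-peak values has a
noise floor of ≈ 4.6 SD that never falls below the 3×SD threshold
criterion, which would make every current look suprathreshold; averaging
first shrinks the floor by 1/√n. The per-epoch aggregation remains
available (`aggregate = "mean_pp"`) for amplitude reporting away from
threshold.

The motor threshold is the smallest current whose amplitude exceeds 3 × the
single-epoch pre-stimulus SD *and* whose successor current also exceeds it.
The two-consecutive rule guards against lone noise spikes on a 131-level
0.1 mA grid. Recovery measured on the synthetic sweeps: within ±0.1 mA at
1 % noise and ±0.3 mA at 10 % noise across thresholds 2.5–4 mA. The
generator defines its threshold parameter as the current at which the
logistic recruitment curve crosses 3 × the configured noise SD, so
generator truth and the estimator contract coincide by construction (with
zero noise the logistic midpoint is used instead, and the 3×SD definition
is vacuous).

## Coactivation

The coactivation coefficient on normalized envelopes `a`, `b` is

\[ C = \frac{\sum_i \min(a_i, b_i)}{\sum_i \max(a_i, b_i)} \]

which is 0 for strictly reciprocal activity, 1 for identical envelopes,
symmetric, bounded, and monotone in burst overlap — exactly the semantics
attached to the "Rudolf coefficient" in this literature, which names the
index but prints no formula. The classical Rudolph et al. style index is
available as `method = "rudolph"`; absolute agreement with any particular
lab's unpublished implementation cannot be guaranteed, so parameter
recovery against the generator is the package's acceptance surface. The
L-shape score of `coordination_profile()` is the fraction of samples with
`min(a, b) < 0.1`: 1 for reciprocal, 0 for fully coactive patterns.

Two calibration choices in the full chain
(`coactivation_table()`) were set by measuring recovery error against
generator truth and are worth stating explicitly:

* **Envelope bandwidth 10 Hz** (not the 5 Hz general-purpose default of
  `envelope()`). Locomotor bursts at a 0.8 s cycle with 30 % duty last
  0.24 s; a 5 Hz fourth-order low-pass smears their edges into the
  antagonist's burst window and inflates the coefficient by ≈ +0.06 even
  without noise. At 10 Hz the full pipeline recovers a truth coefficient of
  0.040 as 0.047 ± 0.001 across seeds at 5 % baseline noise.
* **Resting-baseline subtraction at the lower quartile** inside
  `normalize_envelope()`. Rectified baseline noise has mean
  `σ·√(2/π)` ≈ 4 % of burst amplitude at 5 % noise; without subtraction it
  enters `Σ min` during every burst of the partner muscle and adds ≈ +0.08.
  The lower quartile sits inside the quiet phase whenever a muscle is
  active less than ~75 % of the cycle (true for locomotion) and tracks the
  floor's central level; the 5th percentile does not, because the clipped
  envelope's lower tail is 0.

The synthetic bursts use raised-cosine edges of 0.1 s so that generator
envelopes and pipeline envelopes agree in shape; the closed-form
`Σmin/Σmax` of the noise-free envelopes is stored in the truth sidecar, and
`overlap_for_coactivation()` inverts the overlap→coefficient map by
bisection.

## Gait kinematics

The step period is the lag of the first prominent autocorrelation peak
(prominence floor 0.2, search bounds 0.3–2.0 s for quadrupedal treadmill
gait), refined by parabolic interpolation around the discrete peak. The
recording is tiled with non-overlapping windows of 1.5 periods (windows are
not overlapped so that the per-window ROM values entering median/IQR
summaries are independent), and ROM is max − min angle per window —
deliberately the global extremes of the 1.5-step interval, which differ
from per-identified-step extremes by at most one cycle's drift.

ROM from noisy video is a range statistic and therefore biased upward: at
50 Hz and 0.5° frame jitter, the expected maximum of the handful of
near-peak frames inflates a 10.9° ROM by ≈ +11 %. `summarize_rom()`
therefore exposes a pre-extrema moving average (`smooth_frames`), off by
default so nothing is silently altered. The recommended analysis
configuration for video-rate goniograms is `smooth_frames = 3`: measured
recovery errors at 0.5° jitter are +3.1 %, −0.1 % and +0.4 % for injected
ROMs of 10.9°, 35.6° and 25.0° (raw: +10.8 %, +2.4 %, +3.8 %). ROM is
exactly invariant under angle offsets and sign flips, so goniometer
conventions cannot affect it.

## Statistics

`group_summary()` reports mean ± SEM (sample SD, n−1 denominator), median
and type-7 (linear-interpolation) quartiles — the most common convention,
stated here because quartile methods differ — and Shapiro–Wilk normality
for n ≥ 3. `paired_comparison()` is a two-sided paired t-test; zero-variance
differences are degenerate for the t statistic and resolved by convention
(identical samples → p = 1; an exact constant shift → p = 0), flagged and
warned. No multiple-testing correction is applied, matching the reporting
practice the package mirrors; `run_evoked_pipeline()` callers running many
comparisons should correct externally. Empirical rejection rates of the
paired test match the closed-form noncentral-t power within 3 points at
n ∈ {3, 10} in the acceptance suite.

## What the generators do and do not emulate

The generators reproduce: stimulus-locked compound responses with exact
sub-sample onset latencies and logistic recruitment over 20–1000 Hz
band-limited Gaussian noise; phase-locked antagonist burst envelopes
multiplying independent band-limited carriers; sinusoidal (or mildly
skewed) goniograms with frame jitter; and Gaussian-lobe P1/N1 SSEP
waveforms under 50–250-sweep averaging. Identical config + seed gives
bit-identical output; the seed never leaks into the global RNG stream.

They do not emulate: stimulation artifacts (the analysis chain targets
EES-OFF recordings), powerline harmonics beyond the 50 Hz fundamental,
electrode impedance drift, movement artifacts, polysynaptic late
components, within-session latency drift, or marker-occlusion dropouts in
the kinematics. Passing recovery tests therefore demonstrates estimator
correctness under the stated noise model, not robustness to every artifact
of real recordings.

## Problem sizes used in tests

The shipped test and acceptance problem sizes — 5-stimulus evoked fixtures,
131-level sweeps with 5 stimuli per current, 60 s goniograms at 50 Hz, 30 s
EMG at 4 kHz, 1000-epoch criterion calibrations and 1000-replicate power
checks — were chosen to keep every Monte-Carlo tolerance comfortably
resolvable while the whole suite runs in about a minute.

## A worked example

```{r example, eval = FALSE}
library(neuromotor)

# a synthetic recruitment sweep at a 3 mA threshold
sweep <- make_evoked_recording(evoked_config(
  threshold_ma = 3, currents_ma = rep(seq(1, 14, 0.1), each = 5),
  noise_sd_uv = 30, seed = 1))

curve <- recruitment_curve(sweep$recording, "RF_R")
motor_threshold(curve)
autoplot(curve)

# range of motion of a post-injury hip goniogram
g <- make_goniogram(gonio_config(rom_deg = 10.9, seed = 1))
rs <- summarize_rom(g$goniogram, smooth_frames = 3)
glance(rs)
autoplot(rs)
```
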