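# band-limited Gaussian noise, rescaled to an exact sample SD
bandlimited_noise <- function(n, fs, sd_target, band = c(20, 1000)) {
  if (sd_target <= 0) return(numeric(n))
  w <- rnorm(n)
  bw <- signal::butter(4, band / (fs / 2), type = "pass")
  v <- filtfilt_reflect(bw$b, bw$a, w)
  v / sd(v) * sd_target
}

# unit peak-to-peak evoked-response template as a continuous function of
# normalized time x in (0, 1]; evaluating it at fractional sample offsets keeps
# the injected onset latency exact rather than grid-rounded
response_template_fun <- function(shape = c("biphasic", "damped_sine")) {
  shape <- match.arg(shape)
  raw <- switch(shape,
    biphasic = function(x) sin(2 * pi * x),     # one positive then one negative lobe
    damped_sine = function(x) sin(2 * pi * 2 * x) * exp(-3 * x))
  xs <- seq(0, 1, length.out = 2001)
  pp <- max(raw(xs)) - min(raw(xs))
  function(x) ifelse(x > 0 & x <= 1, raw(x) / pp, 0)
}

#' Configuration for a synthetic evoked-response recording
#'
#' Parameters of [make_evoked_recording()]. Defaults mirror the operating
#' regime of epidural stimulation of the lumbar cord in anaesthetised
#' macaques: 2 Hz single pulses of 250 us, motor thresholds between 2.5 and
#' 4 mA on a 1-14 mA sweep, onset latencies of 3-6 ms, compound responses of
#' a few hundred uV over band-limited (20-1000 Hz) background noise.
#'
#' @param onset_latency_ms response onset latency in ms (> 0).
#' @param shape template shape, `"biphasic"` or `"damped_sine"`.
#' @param duration_ms template duration in ms.
#' @param pp_amplitude_uv template peak-to-peak amplitude at recruitment
#'   saturation, in uV (equals `saturation_uv` unless overridden).
#' @param threshold_ma motor threshold: the current at which the mean
#'   response peak-to-peak crosses `3 x noise_sd_uv` (requires
#'   `noise_sd_uv > 0`; with zero noise the logistic midpoint is used).
#' @param slope_per_ma logistic recruitment slope in 1/mA.
#' @param saturation_uv recruitment saturation amplitude in uV.
#' @param currents_ma stimulus current per event, in mA (one event per
#'   element, in order).
#' @param stim_rate_hz stimulation rate in Hz (default 2).
#' @param pulse_width_us pulse width recorded in the event table (default 250).
#' @param noise_sd_uv background-noise SD in uV.
#' @param sampling_rate sampling rate in Hz (default 4000).
#' @param channel channel label (default `"RF_R"`).
#' @param pre_s quiet lead-in before the first stimulus, in s.
#' @param seed integer seed; same config + seed gives a bit-identical
#'   recording.
#' @return List of class `evoked_config`.
#' @export
evoked_config <- function(onset_latency_ms = 4, shape = "biphasic",
                          duration_ms = 3, pp_amplitude_uv = NULL,
                          threshold_ma = 3, slope_per_ma = 2,
                          saturation_uv = 600,
                          currents_ma = rep(9, 5), stim_rate_hz = 2,
                          pulse_width_us = 250, noise_sd_uv = 30,
                          sampling_rate = 4000, channel = "RF_R",
                          pre_s = 0.2, seed = 1) {
  if (onset_latency_ms <= 0) stop_config("onset_latency_ms must be > 0")
  if (noise_sd_uv < 0) stop_config("noise_sd_uv must be >= 0")
  if (any(currents_ma < 0 | currents_ma > 14))
    stop_config("currents must lie in 0-14 mA")
  if (noise_sd_uv > 0 && 3 * noise_sd_uv >= saturation_uv)
    stop_config("threshold unreachable: 3 x noise_sd >= saturation")
  structure(as.list(environment()), class = "evoked_config")
}

recruitment_amplitude <- function(cfg, current) {
  i50 <- if (cfg$noise_sd_uv > 0) {
    cfg$threshold_ma - qlogis(3 * cfg$noise_sd_uv / cfg$saturation_uv) / cfg$slope_per_ma
  } else cfg$threshold_ma
  cfg$saturation_uv * plogis(cfg$slope_per_ma * (current - i50))
}

#' Synthetic EES-evoked recording with ground truth
#'
#' Generates one EMG channel carrying stimulus-locked compound motor
#' responses over band-limited background noise. Each stimulus at current
#' `I` inserts the response template at `stimulus_time + onset_latency`,
#' scaled by a logistic recruitment curve whose threshold parameter is, by
#' construction, the current at which the response peak-to-peak crosses
#' `3 x noise_sd` (so generator truth and the [motor_threshold()] contract
#' coincide). The event table carries per-event currents.
#'
#' @param cfg an [evoked_config()].
#' @return List with elements `recording` (a [recording()]) and `truth`
#'   (list: all config values plus `i50_ma` and the per-event injected
#'   `amplitude_uv`).
#' @export
make_evoked_recording <- function(cfg) {
  stopifnot(inherits(cfg, "evoked_config"))
  fs <- cfg$sampling_rate
  n_ev <- length(cfg$currents_ma)
  stim_times <- cfg$pre_s + (seq_len(n_ev) - 1L) / cfg$stim_rate_hz
  dur <- cfg$pre_s + n_ev / cfg$stim_rate_hz + 0.1
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs

  withr::with_seed(cfg$seed, {
    v <- bandlimited_noise(n, fs, cfg$noise_sd_uv)
  })
  tmpl_fun <- response_template_fun(cfg$shape)
  dur_s <- ms_to_s(cfg$duration_ms)
  pp <- cfg$pp_amplitude_uv %||% cfg$saturation_uv
  amps <- recruitment_amplitude(cfg, cfg$currents_ma) * pp / cfg$saturation_uv
  for (i in seq_len(n_ev)) {
    onset_s <- stim_times[i] + ms_to_s(cfg$onset_latency_ms)
    i0 <- floor(onset_s * fs) + 1L
    idx <- i0:min(n, i0 + ceiling(dur_s * fs) + 1L)
    x <- (tt[idx] - onset_s) / dur_s
    v[idx] <- v[idx] + amps[i] * tmpl_fun(x)
  }

  sig <- tibble(time_s = tt)
  sig[[cfg$channel]] <- v
  events <- tibble(time_s = stim_times, current_ma = cfg$currents_ma,
                   pulse_width_us = cfg$pulse_width_us, label = "ees_pulse")
  rec <- recording(sig,
                   channels = tibble(label = cfg$channel, kind = "emg", units = "uV"),
                   events = events,
                   meta = list(animal_id = "synthetic", session_id = "evoked",
                               condition = "pre_SCI", ees_state = "off"))
  truth <- c(unclass(cfg),
             list(i50_ma = if (cfg$noise_sd_uv > 0)
               cfg$threshold_ma - qlogis(3 * cfg$noise_sd_uv / cfg$saturation_uv) / cfg$slope_per_ma
               else cfg$threshold_ma,
               amplitude_uv = amps, stim_times_s = stim_times))
  list(recording = rec, truth = truth)
}

# periodic smoothed boxcar envelope on [0, 1) cycle phase
burst_envelope <- function(tt, period, phase, duty, ramp_s = 0.1) {
  ph <- ((tt / period) - phase) %% 1
  ramp <- min(ramp_s / period, duty / 2)
  up <- pmin(1, pmax(0, ph / ramp))
  down <- pmin(1, pmax(0, (duty - ph) / ramp))
  env <- pmin(up, down)
  env[ph >= duty] <- 0
  # raised-cosine shoulders instead of linear ramps
  0.5 - 0.5 * cos(pi * env)
}

#' Configuration for synthetic locomotor EMG
#'
#' Parameters of [make_locomotor_emg()]: an antagonist muscle pair with
#' phase-locked periodic bursts whose support overlap is controlled by a
#' single parameter. Burst edges use raised-cosine ramps of `ramp_s` seconds
#' (default 0.1 s, matched to the 5 Hz analysis-envelope bandwidth so that
#' generator truth and pipeline envelopes agree in shape).
#'
#' @param cycle_period_s gait-cycle period in s (default 0.8).
#' @param duty burst duty cycle as a fraction of the cycle, in (0, 1)
#'   (default 0.3, both muscles).
#' @param amplitude_uv burst amplitude (RMS of the carrier at full
#'   activation) in uV, length 1 or 2.
#' @param antagonist_overlap overlap parameter in `[0, 1]`: 0 places the
#'   second burst in antiphase (disjoint supports), 1 makes the bursts
#'   identical in phase.
#' @param pair channel labels, default `c("TA_R", "GM_R")`.
#' @param carrier_band carrier band in Hz (default `c(20, 1000)`).
#' @param noise_sd_uv baseline (non-burst) noise SD in uV.
#' @param duration_s recording duration in s (>= 3 cycles).
#' @param ramp_s burst edge ramp duration in s.
#' @param sampling_rate sampling rate in Hz (default 4000).
#' @param seed integer seed.
#' @return List of class `gait_emg_config`.
#' @export
gait_emg_config <- function(cycle_period_s = 0.8, duty = 0.3,
                            amplitude_uv = 300, antagonist_overlap = 0,
                            pair = c("TA_R", "GM_R"),
                            carrier_band = c(20, 1000), noise_sd_uv = 15,
                            duration_s = 30, ramp_s = 0.1,
                            sampling_rate = 4000, seed = 1) {
  if (duty <= 0 || duty >= 1) stop_config("duty must lie in (0, 1)")
  if (antagonist_overlap < 0 || antagonist_overlap > 1)
    stop_config("antagonist_overlap must lie in [0, 1]")
  if (duration_s < 3 * cycle_period_s) stop_config("duration must cover >= 3 cycles")
  amplitude_uv <- rep_len(amplitude_uv, 2L)
  structure(as.list(environment()), class = "gait_emg_config")
}

#' Synthetic locomotor EMG for an antagonist pair, with ground truth
#'
#' Two EMG channels whose activation envelopes are periodic smoothed boxcars:
#' muscle A bursts at cycle phase 0, muscle B at a phase offset interpolating
#' from antiphase (overlap 0) to in-phase (overlap 1). The signal is the
#' envelope multiplied by band-limited Gaussian carrier noise plus baseline
#' noise. The truth sidecar carries the exact noise-free envelopes and their
#' min/max-sum coactivation coefficient, so downstream estimates can be
#' scored without re-deriving anything.
#'
#' @param cfg a [gait_emg_config()].
#' @return List with `recording` and `truth` (config values plus
#'   `envelope_a`, `envelope_b`, `coactivation`, `phase_b`).
#' @export
make_locomotor_emg <- function(cfg) {
  stopifnot(inherits(cfg, "gait_emg_config"))
  fs <- cfg$sampling_rate
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1L) / fs
  phase_b <- (1 - cfg$antagonist_overlap) * 0.5
  env_a <- burst_envelope(tt, cfg$cycle_period_s, 0, cfg$duty, cfg$ramp_s)
  env_b <- burst_envelope(tt, cfg$cycle_period_s, phase_b, cfg$duty, cfg$ramp_s)
  truth_coef <- sum(pmin(env_a, env_b)) / sum(pmax(env_a, env_b))

  withr::with_seed(cfg$seed, {
    car_a <- bandlimited_noise(n, fs, 1, cfg$carrier_band)
    car_b <- bandlimited_noise(n, fs, 1, cfg$carrier_band)
    base_a <- bandlimited_noise(n, fs, cfg$noise_sd_uv, cfg$carrier_band)
    base_b <- bandlimited_noise(n, fs, cfg$noise_sd_uv, cfg$carrier_band)
  })
  sig <- tibble(time_s = tt)
  sig[[cfg$pair[1]]] <- cfg$amplitude_uv[1] * env_a * car_a + base_a
  sig[[cfg$pair[2]]] <- cfg$amplitude_uv[2] * env_b * car_b + base_b
  rec <- recording(sig,
                   channels = tibble(label = cfg$pair, kind = "emg", units = "uV"),
                   meta = list(animal_id = "synthetic", session_id = "locomotor",
                               condition = "pre_SCI", ees_state = "off"))
  list(recording = rec,
       truth = c(unclass(cfg),
                 list(envelope_a = env_a, envelope_b = env_b,
                      coactivation = truth_coef, phase_b = phase_b)))
}

#' Overlap parameter realising a target coactivation coefficient
#'
#' Inverts the generator mapping: finds the `antagonist_overlap` value whose
#' noise-free envelopes have min/max-sum coefficient equal to `target`
#' (monotone search by bisection on the generator's own truth coefficient).
#'
#' @param target desired coefficient in `[0, 1)`.
#' @param cfg a [gait_emg_config()] providing all other parameters.
#' @param tol bisection tolerance on the coefficient (default 1e-4).
#' @return Overlap parameter in `[0, 1]`.
#' @export
overlap_for_coactivation <- function(target, cfg = gait_emg_config(), tol = 1e-4) {
  coef_of <- function(o) {
    n <- round(20 * cfg$cycle_period_s * cfg$sampling_rate / 4)  # 20 cycles, fs/4 enough
    fs4 <- cfg$sampling_rate / 4
    tt <- (seq_len(n) - 1L) / fs4
    pb <- (1 - o) * 0.5
    ea <- burst_envelope(tt, cfg$cycle_period_s, 0, cfg$duty, cfg$ramp_s)
    eb <- burst_envelope(tt, cfg$cycle_period_s, pb, cfg$duty, cfg$ramp_s)
    sum(pmin(ea, eb)) / sum(pmax(ea, eb))
  }
  lo <- 0; hi <- 1
  if (target <= coef_of(0)) return(0)
  if (target >= 1) stop_param("target must be < 1")
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (coef_of(mid) < target) lo <- mid else hi <- mid
    if (abs(coef_of(mid) - target) < tol) return(mid)
  }
  (lo + hi) / 2
}

#' Configuration for a synthetic goniogram
#'
#' @param cycle_period_s step-cycle period in s (default 0.8).
#' @param rom_deg per-cycle range of motion in degrees (>= 0).
#' @param midline_deg mean joint angle in degrees.
#' @param waveform `"sine"` (default) or `"skewed"` (faster extension than
#'   flexion, closer to real gait).
#' @param angle_noise_sd_deg frame-jitter SD in degrees.
#' @param frame_rate_hz video frame rate in Hz (default 50; must give
#'   >= 8 frames per cycle).
#' @param duration_s duration in s (default 60).
#' @param joint,side labels recorded in the output.
#' @param seed integer seed.
#' @return List of class `gonio_config`.
#' @export
gonio_config <- function(cycle_period_s = 0.8, rom_deg = 20, midline_deg = 100,
                         waveform = c("sine", "skewed"),
                         angle_noise_sd_deg = 0.5, frame_rate_hz = 50,
                         duration_s = 60, joint = "hip", side = "right",
                         seed = 1) {
  waveform <- match.arg(waveform)
  if (rom_deg < 0) stop_config("rom_deg must be >= 0")
  if (frame_rate_hz * cycle_period_s < 8)
    stop_config("frame rate too low: need >= 8 frames per cycle")
  structure(as.list(environment()), class = "gonio_config")
}

#' Synthetic goniogram with ground truth
#'
#' Joint-angle trace `midline + (rom/2) * w(t/period) + noise` with `w` a
#' unit-amplitude periodic waveform sampled at video rate.
#'
#' @param cfg a [gonio_config()].
#' @return List with `goniogram` (tibble `time_s`, `angle_deg`, with
#'   attributes `joint` and `side`) and `truth` (config values).
#' @export
make_goniogram <- function(cfg) {
  stopifnot(inherits(cfg, "gonio_config"))
  n <- round(cfg$duration_s * cfg$frame_rate_hz)
  tt <- (seq_len(n) - 1L) / cfg$frame_rate_hz
  ph <- 2 * pi * tt / cfg$cycle_period_s
  w <- switch(cfg$waveform,
              sine = sin(ph),
              skewed = {
                raw <- sin(ph) + 0.3 * sin(2 * ph)
                2 * (raw - min(raw)) / (max(raw) - min(raw)) - 1
              })
  withr::with_seed(cfg$seed, {
    noise <- rnorm(n, sd = cfg$angle_noise_sd_deg)
  })
  g <- tibble(time_s = tt,
              angle_deg = cfg$midline_deg + cfg$rom_deg / 2 * w + noise)
  attr(g, "joint") <- cfg$joint
  attr(g, "side") <- cfg$side
  list(goniogram = g, truth = unclass(cfg))
}

#' Configuration for a synthetic SSEP recording
#'
#' @param p1_latency_ms,n1_latency_ms latencies of the first positive and
#'   first negative cortical component in ms (`p1 < n1`).
#' @param p1n1_amplitude_uv peak-to-peak amplitude between P1 and N1 in uV.
#' @param lobe_width_ms Gaussian half-width of each component lobe in ms.
#' @param n_sweeps number of stimulus sweeps (50-250 is the usual averaging
#'   range).
#' @param sweep_noise_sd_uv per-sweep noise SD in uV.
#' @param stim_rate_hz stimulation rate in Hz (default 3.4).
#' @param window_ms epoch span that must contain both components,
#'   `c(pre, post)` in ms.
#' @param sampling_rate sampling rate in Hz.
#' @param seed integer seed.
#' @return List of class `ssep_config`.
#' @export
ssep_config <- function(p1_latency_ms = 17.54, n1_latency_ms = 25,
                        p1n1_amplitude_uv = 6.7, lobe_width_ms = 2.5,
                        n_sweeps = 100, sweep_noise_sd_uv = 2,
                        stim_rate_hz = 3.4, window_ms = c(-10, 50),
                        sampling_rate = 4000, seed = 1) {
  if (p1_latency_ms >= n1_latency_ms) stop_config("need p1_latency < n1_latency")
  if (n_sweeps < 1) stop_config("n_sweeps must be >= 1")
  if (n1_latency_ms >= window_ms[2] || p1_latency_ms <= window_ms[1])
    stop_config("component latencies must lie inside the epoch window")
  structure(as.list(environment()), class = "ssep_config")
}

#' Synthetic SSEP recording with ground truth
#'
#' A cortical channel carrying `n_sweeps` noisy repetitions of a P1/N1
#' waveform (two opposed Gaussian lobes at the configured latencies, scaled
#' so the P1-N1 difference equals the configured amplitude), with stimulus
#' events at the sweep times.
#'
#' @param cfg an [ssep_config()].
#' @return List with `recording` and `truth`.
#' @export
make_ssep_recording <- function(cfg) {
  stopifnot(inherits(cfg, "ssep_config"))
  fs <- cfg$sampling_rate
  isi <- 1 / cfg$stim_rate_hz
  pre <- 0.1
  dur <- pre + cfg$n_sweeps * isi + 0.1
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1L) / fs

  w <- ms_to_s(cfg$lobe_width_ms)
  shape <- function(t_rel)
    exp(-(t_rel - ms_to_s(cfg$p1_latency_ms))^2 / (2 * w^2)) -
    exp(-(t_rel - ms_to_s(cfg$n1_latency_ms))^2 / (2 * w^2))
  u_p1 <- shape(ms_to_s(cfg$p1_latency_ms))
  u_n1 <- shape(ms_to_s(cfg$n1_latency_ms))
  scale <- cfg$p1n1_amplitude_uv / (u_p1 - u_n1)

  stim_times <- pre + (seq_len(cfg$n_sweeps) - 1L) * isi
  withr::with_seed(cfg$seed, {
    v <- bandlimited_noise(n, fs, cfg$sweep_noise_sd_uv, c(10, 1000))
  })
  tmpl_len <- round(ms_to_s(cfg$window_ms[2]) * fs)
  t_rel <- (seq_len(tmpl_len) - 1L) / fs
  tmpl <- scale * shape(t_rel)
  for (s in stim_times) {
    i0 <- round(s * fs) + 1L
    idx <- i0:(i0 + tmpl_len - 1L)
    v[idx] <- v[idx] + tmpl
  }
  sig <- tibble(time_s = tt, Cz_Fz = v)
  rec <- recording(sig,
                   channels = tibble(label = "Cz_Fz", kind = "neural", units = "uV"),
                   events = tibble(time_s = stim_times, label = "nerve_stim"),
                   meta = list(animal_id = "synthetic", session_id = "ssep",
                               condition = "pre_SCI", ees_state = "off"))
  list(recording = rec,
       truth = c(unclass(cfg), list(stim_times_s = stim_times)))
}
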