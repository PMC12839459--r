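test_that("generators are deterministic in the seed and vary across seeds", {
  a <- make_evoked_recording(evoked_config(seed = 5))
  b <- make_evoked_recording(evoked_config(seed = 5))
  c <- make_evoked_recording(evoked_config(seed = 6))
  expect_identical(a$recording$signals, b$recording$signals)
  expect_false(identical(a$recording$signals$RF_R, c$recording$signals$RF_R))
  expect_equal(a$truth$amplitude_uv, c$truth$amplitude_uv)  # same ground truth

  g1 <- make_goniogram(gonio_config(seed = 2))
  g2 <- make_goniogram(gonio_config(seed = 2))
  expect_identical(g1$goniogram, g2$goniogram)

  l1 <- make_locomotor_emg(gait_emg_config(duration_s = 4, seed = 3))
  l2 <- make_locomotor_emg(gait_emg_config(duration_s = 4, seed = 3))
  expect_identical(l1$recording$signals, l2$recording$signals)

  s1 <- make_ssep_recording(ssep_config(n_sweeps = 10, seed = 4))
  s2 <- make_ssep_recording(ssep_config(n_sweeps = 10, seed = 4))
  expect_identical(s1$recording$signals, s2$recording$signals)
})

test_that("generators do not disturb the global RNG stream", {
  withr::with_seed(1234, {
    r1 <- rnorm(1)
  })
  withr::with_seed(1234, {
    invisible(make_evoked_recording(evoked_config(seed = 9)))
    r2 <- rnorm(1)
  })
  expect_identical(r1, r2)
})

test_that("noise-free evoked amplitude equals the recruitment sigmoid exactly", {
  cfg <- evoked_config(noise_sd_uv = 0, currents_ma = 9, threshold_ma = 3,
                       slope_per_ma = 2, saturation_uv = 600, seed = 1)
  sim <- make_evoked_recording(cfg)
  eps <- extract_epochs(sim$recording, "RF_R")
  expected <- 600 * stats::plogis(2 * (9 - 3))      # i50 = threshold when noise = 0
  expect_equal(peak_to_peak(eps, c(3, 30)), expected, tolerance = 1e-3)
  expect_equal(sim$truth$amplitude_uv[1], expected, tolerance = 1e-9)
})

test_that("at 0 mA the measured amplitude sits at the noise floor", {
  sim <- make_evoked_recording(evoked_config(currents_ma = rep(c(0, 9), each = 5),
                                             noise_sd_uv = 30, seed = 12))
  cv <- recruitment_curve(sim$recording, "RF_R")
  amp0 <- cv$amplitude_pp_uv[cv$current_ma == 0]
  amp9 <- cv$amplitude_pp_uv[cv$current_ma == 9]
  # averaged-noise range is far below the suprathreshold response
  expect_lt(amp0, 6 * 30 / sqrt(5))
  expect_gt(amp9 / amp0, 5)
})

test_that("evoked config rejects invalid regimes", {
  expect_error(evoked_config(currents_ma = c(2, 15)),
               class = "neuromotor_config_error")
  expect_error(evoked_config(onset_latency_ms = -1),
               class = "neuromotor_config_error")
  expect_error(evoked_config(noise_sd_uv = 300, saturation_uv = 600),
               class = "neuromotor_config_error")
})

test_that("locomotor truth coefficient hits the extremes and inverts cleanly", {
  s0 <- make_locomotor_emg(gait_emg_config(antagonist_overlap = 0,
                                           duration_s = 4, seed = 1))
  expect_equal(s0$truth$coactivation, 0)
  expect_equal(coactivation_index(s0$truth$envelope_a,
                                  s0$truth$envelope_b)$coefficient, 0)
  s1 <- make_locomotor_emg(gait_emg_config(antagonist_overlap = 1,
                                           duration_s = 4, seed = 1))
  expect_equal(s1$truth$coactivation, 1)
  # inversion: overlap_for_coactivation followed by the generator reproduces
  # the requested coefficient
  o <- overlap_for_coactivation(0.29, gait_emg_config())
  sim <- make_locomotor_emg(gait_emg_config(antagonist_overlap = o, seed = 2))
  expect_lt(abs(sim$truth$coactivation - 0.29), 0.005)
  expect_error(gait_emg_config(duration_s = 1),
               class = "neuromotor_config_error")
})

test_that("goniogram generator respects its frame-rate contract and rom truth", {
  expect_error(gonio_config(frame_rate_hz = 5),
               class = "neuromotor_config_error")
  sim <- make_goniogram(gonio_config(rom_deg = 0, angle_noise_sd_deg = 0.3,
                                     duration_s = 20, seed = 3))
  # rom 0: only the noise floor remains; period undetectable but rom small
  expect_lt(diff(range(sim$goniogram$angle_deg)), 3)
  # period recovery across frame rates
  for (fr in c(25, 50, 100)) {
    g <- make_goniogram(gonio_config(frame_rate_hz = fr, duration_s = 30,
                                     seed = fr))$goniogram
    expect_lt(abs(estimate_step_period(g) - 0.8) / 0.8, 0.05)
  }
})

test_that("ssep generator recovers exactly in the noise-free limit", {
  sim <- make_ssep_recording(ssep_config(sweep_noise_sd_uv = 0, n_sweeps = 50,
                                         seed = 1))
  avg <- average_epochs(extract_epochs(sim$recording, "Cz_Fz"), n = 50)
  f <- ssep_features(avg)
  expect_lt(abs(f$p1_latency_ms - 17.54), 0.26)      # one sample at 4 kHz + grid
  expect_lt(abs(f$n1_latency_ms - 25), 0.26)
  # the 150 Hz peak-finding smoother attenuates the lobes by ~2 %
  expect_lt(abs(f$p1n1_amplitude_uv - 6.7) / 6.7, 0.03)
  expect_error(ssep_config(p1_latency_ms = 30, n1_latency_ms = 20),
               class = "neuromotor_config_error")
})

test_that("averaged ssep detection succeeds with sweep noise equal to the amplitude", {
  hits <- vapply(1:20, function(sd) {
    sim <- make_ssep_recording(ssep_config(sweep_noise_sd_uv = 6.7,
                                           n_sweeps = 250, seed = 400 + sd))
    avg <- average_epochs(extract_epochs(sim$recording, "Cz_Fz"), n = 250)
    ssep_features(avg)$present
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
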