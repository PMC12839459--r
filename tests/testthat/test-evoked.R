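evoked_fixture <- function(...) make_evoked_recording(evoked_config(...))

test_that("epoching is time-locked, half-open, and matches direct indexing", {
  ev <- tibble::tibble(time_s = 0.2 + (0:9) / 2)
  rec <- make_sine_recording(c(RF_R = 7), dur = 6, events = ev)
  eps <- extract_epochs(rec, "RF_R", window = c(-10, 50))
  expect_equal(length(unique(eps$epoch)), 10)
  expect_equal(sum(eps$epoch == 1), 240)            # 60 ms x 4 kHz
  # direct-indexing oracle: epoch 3 equals the raw slice of the source trace
  i0 <- round((ev$time_s[3] - 0.010) * 4000) + 1
  expect_equal(eps$value_uv[eps$epoch == 3], rec$signals$RF_R[i0:(i0 + 239)])
})

test_that("out-of-bounds epochs are dropped with a warning", {
  ev <- tibble::tibble(time_s = c(0.2 + (0:8) / 2, 5.995))
  rec <- make_sine_recording(c(RF_R = 7), dur = 6, events = ev)
  expect_warning(eps <- extract_epochs(rec, "RF_R"), "dropped 1")
  expect_equal(length(unique(eps$epoch)), 9)
  ev_all_out <- tibble::tibble(time_s = 5.999)
  expect_error(suppressWarnings(extract_epochs(rec, "RF_R", ev_all_out)),
               class = "neuromotor_data_error")
})

test_that("epoch averaging is the pointwise mean with variance reduction ~1/sqrt(5)", {
  ev <- tibble::tibble(time_s = 0.2 + (0:4) / 2)
  rec <- make_sine_recording(c(RF_R = 40), dur = 3, events = ev)
  eps <- extract_epochs(rec, "RF_R")
  avg <- average_epochs(eps, n = 5)
  # identical epochs (periodic trace, events at integer cycle counts): average == epoch
  expect_equal(avg$value_uv, eps$value_uv[eps$epoch == 1], tolerance = 1e-10)
  expect_error(average_epochs(eps, n = 6), class = "neuromotor_data_error")

  # x and -x average to zero
  eps2 <- eps[eps$epoch %in% 1:2, ]
  eps2$value_uv[eps2$epoch == 2] <- -eps2$value_uv[eps2$epoch == 1]
  expect_equal(max(abs(average_epochs(eps2, n = 2)$value_uv)), 0)

  # Monte-Carlo: residual SD of a 5-epoch average of template + noise ~ sd/sqrt(5)
  resid_sd <- withr::with_seed(42, {
    template <- sin(2 * pi * (1:240) / 60)
    replicate(40, {
      m <- replicate(5, template + rnorm(240, sd = 2))
      sd(rowMeans(m) - template)
    })
  })
  expect_lt(abs(mean(resid_sd) - 2 / sqrt(5)) / (2 / sqrt(5)), 0.25)
})

test_that("peak-to-peak amplitude is max minus min in the window", {
  ep <- tibble::tibble(time_ms = seq(-10, 49.75, by = 0.25),
                       value_uv = 0)
  ep$value_uv[ep$time_ms == 10] <- 30
  ep$value_uv[ep$time_ms == 12] <- -20
  expect_equal(peak_to_peak(ep, c(3, 30)), 50)
  expect_equal(peak_to_peak(ep, c(30, 45)), 0)
  expect_error(peak_to_peak(ep, c(100, 110)), class = "neuromotor_parameter_error")
})

test_that("amplitude recovery from an injected template is within 3%", {
  sim <- evoked_fixture(onset_latency_ms = 4, saturation_uv = 1000,
                        currents_ma = rep(12, 5), noise_sd_uv = 10, seed = 5)
  eps <- extract_epochs(sim$recording, "RF_R")
  avg <- average_epochs(eps, n = 5)
  inj <- sim$truth$amplitude_uv[1]
  expect_lt(abs(peak_to_peak(avg, c(3, 30)) - inj) / inj, 0.03)
})

test_that("the 3xSD presence criterion follows its arithmetic and is scale-invariant", {
  base <- tibble::tibble(time_ms = seq(-10, 49.75, by = 0.25), value_uv = 0)
  base$value_uv[base$time_ms < 0] <- rep(c(-2, 2), 20)   # noise sd ~2.03
  nsd <- sd(base$value_uv[base$time_ms < 0])
  hit <- base
  hit$value_uv[hit$time_ms == 10] <- 3.5 * nsd            # pp 3.5 sd > 3 sd
  expect_true(detect_response(hit)$present)
  miss <- base
  miss$value_uv[miss$time_ms == 10] <- 2.5 * nsd
  expect_false(detect_response(miss)$present)
  # scale invariance
  for (c_mult in c(0.01, 1, 250)) {
    sc <- hit; sc$value_uv <- sc$value_uv * c_mult
    expect_true(detect_response(sc)$present)
  }
  expect_error(detect_response(hit, noise_window = c(-10, 0), response_window = c(-5, 30)),
               class = "neuromotor_parameter_error")
})

test_that("onset latency recovers an injected onset to within one sample", {
  sim <- evoked_fixture(onset_latency_ms = 3.0, currents_ma = rep(9, 5),
                        noise_sd_uv = 6, seed = 8)        # high SNR (1% of 600)
  eps <- extract_epochs(sim$recording, "RF_R")
  lat <- onset_latency(eps)
  expect_true(all(abs(lat$latency_ms - 3.0) <= 0.25))
  # flat epoch -> absent
  flat <- tibble::tibble(time_ms = seq(-10, 49.75, by = 0.25), value_uv = 0)
  expect_warning(res <- onset_latency(flat), "degenerate")
  expect_true(is.na(res$latency_ms))
})

test_that("onset latency is invariant under baseline offset", {
  sim <- evoked_fixture(onset_latency_ms = 4.2, currents_ma = rep(9, 3),
                        noise_sd_uv = 12, seed = 9)
  eps <- extract_epochs(sim$recording, "RF_R")
  shifted <- eps
  shifted$value_uv <- shifted$value_uv + 500
  expect_equal(onset_latency(eps)$latency_ms, onset_latency(shifted)$latency_ms)
})

test_that("latencies generated in the 3-6 ms physiological regime stay in it", {
  lats <- c(3.2, 4.1, 4.9, 5.6)
  for (i in seq_along(lats)) {
    sim <- evoked_fixture(onset_latency_ms = lats[i], currents_ma = rep(9, 5),
                          noise_sd_uv = 30, seed = 20 + i)
    est <- onset_latency(extract_epochs(sim$recording, "RF_R"))$latency_ms
    expect_true(all(est >= 3 & est <= 6))
  }
})

test_that("ssep features recover injected P1/N1 and reject pure noise", {
  sim <- make_ssep_recording(ssep_config(seed = 2))
  avg <- average_epochs(extract_epochs(sim$recording, "Cz_Fz"), n = 100)
  f <- ssep_features(avg)
  expect_true(f$present)
  expect_lt(abs(f$p1_latency_ms - 17.54), 0.5)
  expect_lt(abs(f$n1_latency_ms - 25), 0.5)
  expect_lt(abs(f$p1n1_amplitude_uv - 6.7) / 6.7, 0.1)

  # pure-noise averages are declared absent (seeded)
  fp <- vapply(1:10, function(sd) {
    simz <- make_ssep_recording(ssep_config(p1n1_amplitude_uv = 0, seed = 300 + sd))
    avgz <- average_epochs(extract_epochs(simz$recording, "Cz_Fz"), n = 100)
    ssep_features(avgz)$present
  }, logical(1))
  expect_lt(mean(fp), 0.2)

  # inverted polarity swaps the roles but keeps the amplitude magnitude
  inv <- avg
  inv$value_uv <- -inv$value_uv
  fi <- ssep_features(inv)
  expect_lt(abs(fi$p1n1_amplitude_uv - f$p1n1_amplitude_uv) / f$p1n1_amplitude_uv, 0.15)
  expect_gt(fi$p1_latency_ms, f$p1_latency_ms)      # old N1 lobe becomes P1
})

test_that("recruitment curves are ascending in current and monotone under low noise", {
  sweep <- rep(seq(1, 14, 0.5), each = 3)
  shuffled <- withr::with_seed(99, sample(sweep))
  sim <- evoked_fixture(threshold_ma = 3, noise_sd_uv = 6,
                        currents_ma = shuffled, seed = 31)
  # events must be strictly increasing in time; currents arrive shuffled
  cv <- recruitment_curve(sim$recording, "RF_R")
  expect_false(is.unsorted(cv$current_ma))
  # monotone nondecreasing within noise tolerance
  expect_true(all(diff(cv$amplitude_pp_uv) > -3 * attr(cv, "noise_sd_uv")))
  expect_error(recruitment_curve(sim$recording, "RF_R",
                                 events = tibble::tibble(time_s = c(0.2, 0.7))),
               class = "neuromotor_data_error")
})

test_that("motor threshold applies the two-consecutive rule", {
  curve <- tibble::tibble(current_ma = seq(1, 2, 0.1),
                          amplitude_pp_uv = c(1, 1, 40, 1, 1, 1, 35, 40, 50, 60, 80),
                          n_epochs = 5)
  class(curve) <- c("recruitment_curve", class(tibble::tibble()))
  attr(curve, "noise_sd_uv") <- 10
  expect_equal(motor_threshold(curve), 1.6)          # lone spike at 1.2 skipped
  low <- curve
  low$amplitude_pp_uv <- rep(5, 11)                  # all below 30
  expect_true(is.na(motor_threshold(low)))
})

test_that("threshold recovery: within 0.1 mA at low noise, 0.3 mA at 10% noise", {
  for (thr in c(2.5, 3.2, 4.0)) {
    sim_lo <- evoked_fixture(threshold_ma = thr, noise_sd_uv = 6,
                             currents_ma = rep(seq(1, 14, 0.1), each = 5),
                             seed = round(thr * 10))
    est_lo <- motor_threshold(recruitment_curve(sim_lo$recording, "RF_R"))
    expect_lt(abs(est_lo - thr), 0.1 + 1e-9)
    sim_hi <- evoked_fixture(threshold_ma = thr, noise_sd_uv = 60,
                             currents_ma = rep(seq(1, 14, 0.1), each = 5),
                             seed = round(thr * 10) + 1)
    est_hi <- motor_threshold(recruitment_curve(sim_hi$recording, "RF_R"))
    expect_lt(abs(est_hi - thr), 0.3 + 1e-9)
  }
})

test_that("estimation error shrinks as noise goes to zero", {
  noise_ladder <- c(60, 30, 6)
  errs <- vapply(noise_ladder, function(ns) {
    sim <- evoked_fixture(onset_latency_ms = 4.58, currents_ma = rep(9, 5),
                          noise_sd_uv = ns, seed = 77)
    mean(abs(onset_latency(extract_epochs(sim$recording, "RF_R"))$latency_ms - 4.58))
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 0.2)
})
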