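sine_gonio <- function(period = 0.8, amp = 10, fs = 50, dur = 60, mid = 100,
                       noise = 0, seed = 1, drift = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  noise_v <- if (noise > 0) withr::with_seed(seed, rnorm(length(t), sd = noise)) else 0
  tibble::tibble(time_s = t,
                 angle_deg = mid + amp * sin(2 * pi * t / period) +
                   drift * t + noise_v)
}

test_that("step period is recovered from clean and noisy goniograms", {
  g <- sine_gonio(period = 0.8)
  expect_lt(abs(estimate_step_period(g) - 0.8), 1 / 50)
  expect_error(estimate_step_period(tibble::tibble(time_s = (0:999) / 50,
                                                   angle_deg = 90)),
               class = "neuromotor_data_error")
  # SNR 10 in amplitude: noise sd = amp/10
  for (sd_i in 1:5) {
    gn <- sine_gonio(period = 0.73, amp = 10, noise = 1, seed = sd_i)
    expect_lt(abs(estimate_step_period(gn) - 0.73) / 0.73, 0.05)
  }
})

test_that("windows tile the recording without overlap", {
  g <- sine_gonio(dur = 60)
  w <- segment_windows(g, period = 0.8, factor = 1.5)
  expect_equal(nrow(w), 50)                          # floor(60 / 1.2)
  expect_equal(w$stop_s - w$start_s, rep(1.2, 50))
  expect_equal(w$start_s[-1], w$stop_s[-50])         # contiguous, disjoint
  expect_lte(max(w$stop_s), 60 + 1e-9)
  expect_error(segment_windows(sine_gonio(dur = 1), period = 0.8, factor = 1.5),
               class = "neuromotor_data_error")
})

test_that("per-window ROM equals max minus min, drift bounded by closed form", {
  g <- sine_gonio(amp = 10, dur = 10)
  expect_equal(rom_per_window(g, c(0, 1.2)), 20, tolerance = 0.02)
  gc <- tibble::tibble(time_s = (0:499) / 50, angle_deg = 42)
  expect_equal(rom_per_window(gc, c(0, 1.2)), 0)
  # adding 0.5 deg/s drift over a 1.2 s window inflates ROM by at most 0.6 deg
  gd <- sine_gonio(amp = 10, dur = 10, drift = 0.5)
  r <- rom_per_window(gd, c(0, 1.2))
  expect_gte(r, 20 - 0.05)
  expect_lte(r, 20.6 + 0.05)
})

test_that("summarize_rom recovers a constant injected ROM within 2% (noise-free)", {
  sim <- make_goniogram(gonio_config(rom_deg = 24, angle_noise_sd_deg = 0, seed = 1))
  rs <- summarize_rom(sim$goniogram)
  expect_lt(abs(rs$mean_rom - 24) / 24, 0.02)
  expect_equal(rs$n_windows, 50)
  expect_lt(abs(rs$period - 0.8), 0.02)
})

test_that("two-regime traces give a median between regimes and a bimodal profile", {
  g1 <- make_goniogram(gonio_config(rom_deg = 30, angle_noise_sd_deg = 0,
                                    duration_s = 30, seed = 1))$goniogram
  g2 <- make_goniogram(gonio_config(rom_deg = 10, angle_noise_sd_deg = 0,
                                    duration_s = 30, seed = 1))$goniogram
  g2$time_s <- g2$time_s + 30
  rs <- summarize_rom(dplyr::bind_rows(g1, g2), duration = 60)
  expect_gt(rs$median_rom, 10)
  expect_lt(rs$median_rom, 30)
  roms <- tidy(rs)$rom_deg
  expect_gt(sum(abs(roms - 30) < 1), 10)
  expect_gt(sum(abs(roms - 10) < 1), 10)
})

test_that("ROM is invariant under offset and sign flip", {
  sim <- make_goniogram(gonio_config(rom_deg = 18, seed = 3))
  g <- sim$goniogram
  rs <- summarize_rom(g)
  g_off <- g; g_off$angle_deg <- g_off$angle_deg + 37.5
  g_neg <- g; g_neg$angle_deg <- -g_neg$angle_deg
  expect_equal(summarize_rom(g_off)$per_window$rom_deg, rs$per_window$rom_deg)
  expect_equal(summarize_rom(g_neg)$per_window$rom_deg, rs$per_window$rom_deg)
})

test_that("mean ROM is monotone in the injected ROM", {
  means <- vapply(c(5, 15, 30, 50), function(r) {
    sim <- make_goniogram(gonio_config(rom_deg = r, duration_s = 30, seed = 4))
    summarize_rom(sim$goniogram, duration = 30, smooth_frames = 3)$mean_rom
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("noise-induced ROM bias is positive and shrinks with the noise", {
  biases <- vapply(c(2, 1, 0.25), function(ns) {
    sim <- make_goniogram(gonio_config(rom_deg = 20, angle_noise_sd_deg = ns,
                                       duration_s = 30, seed = 6))
    summarize_rom(sim$goniogram, duration = 30)$mean_rom - 20
  }, numeric(1))
  expect_true(all(biases > 0))
  expect_true(all(diff(biases) < 0))
})
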