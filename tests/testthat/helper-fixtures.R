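# fixtures built in code; all randomness goes through explicit seeds

make_sine_recording <- function(freqs = c(TA_R = 10), fs = 4000, dur = 1,
                                amp = 100, events = NULL) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  sig <- tibble::tibble(time_s = t)
  for (nm in names(freqs)) sig[[nm]] <- amp * sin(2 * pi * freqs[[nm]] * t)
  recording(sig, events = events,
            meta = list(animal_id = "m1", session_id = "s1",
                        condition = "pre_SCI", ees_state = "off"))
}

# attenuation of a pure tone through a filter, in dB (negative = attenuated)
tone_attenuation_db <- function(filter_fun, freq, fs = 4000, dur = 5) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- sin(2 * pi * freq * t)
  y <- filter_fun(x)
  core <- seq(round(0.1 * length(x)), round(0.9 * length(x)))
  20 * log10(sqrt(mean(y[core]^2)) / sqrt(mean(x[core]^2)))
}

expect_tbl_named <- function(x, cols) {
  expect_s3_class(x, "tbl_df")
  expect_true(all(cols %in% names(x)))
}
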