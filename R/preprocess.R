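#' EMG filter specification
#'
#' Conditioning parameters for raw EMG: a 50 Hz mains notch and a 20-1000 Hz
#' band-pass, the band used for intramuscular EMG sampled at 4 kHz. The filter
#' family is a 4th-order Butterworth band-pass plus a 2nd-order IIR notch
#' (quality factor 30), both applied forward-backward (zero phase) so that
#' onset latencies are not delayed by filtering.
#'
#' @param notch_freq notch centre frequency in Hz (default 50).
#' @param notch_q dimensionless notch quality factor (default 30).
#' @param band_low,band_high band-pass edges in Hz (defaults 20 and 1000).
#' @param order Butterworth order of the band-pass (default 4).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        band_low = 20, band_high = 1000, order = 4) {
  if (!(band_low > 0 && band_low < band_high)) stop_param("need 0 < band_low < band_high")
  if (notch_q <= 0) stop_param("notch_q must be > 0")
  if (order < 1) stop_param("order must be >= 1")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 band_low = band_low, band_high = band_high, order = order),
            class = "filter_spec")
}

# zero-phase forward-backward IIR application with reflect padding of
# 3 * (ncoef - 1) samples, so startup transients never reach the signal
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L))
  if (pad > 0) {
    head_pad <- 2 * x[1] - x[(pad + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xp <- c(head_pad, x, tail_pad)
  } else xp <- x
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

# RBJ biquad notch coefficients (the signal package ships no IIR notch designer)
notch_coef <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

apply_to_channels <- function(x, channels, fun) {
  stopifnot(inherits(x, "recording"))
  if (is.null(channels))
    channels <- x$channels$label[x$channels$kind %in% c("emg", "neural")]
  for (ch in channels) {
    if (!ch %in% x$channels$label) stop_data(paste0("no such channel: '", ch, "'"))
    x$signals[[ch]] <- fun(x$signals[[ch]])
  }
  x
}

#' Zero-phase mains notch filter
#'
#' Removes the 50 Hz powerline component with a second-order IIR notch applied
#' forward-backward. Output has the same length and sampling rate as the
#' input.
#'
#' @param x a [recording()] (filters EMG/neural channels) or a numeric vector.
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz; required when `x` is a numeric vector.
#' @param channels channels to filter when `x` is a recording (default: all
#'   EMG and neural channels).
#' @return Same type as `x`.
#' @export
notch_filter <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  UseMethod("notch_filter")
}

#' @export
notch_filter.numeric <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  if (!is_number(fs)) stop_param("fs required for numeric input")
  if (spec$notch_freq >= fs / 2) stop_param("notch frequency must be below Nyquist")
  co <- notch_coef(spec$notch_freq, fs, spec$notch_q)
  filtfilt_reflect(co$b, co$a, x)
}

#' @export
notch_filter.recording <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  fs <- x$sampling_rate
  apply_to_channels(x, channels, function(v) notch_filter.numeric(v, spec, fs))
}

#' Zero-phase band-pass filter
#'
#' Butterworth band-pass (default 20-1000 Hz, order 4) applied
#' forward-backward. Rejects DC and sub-band drift; output length equals input
#' length.
#'
#' @inheritParams notch_filter
#' @return Same type as `x`.
#' @export
bandpass_filter <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  UseMethod("bandpass_filter")
}

#' @export
bandpass_filter.numeric <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  if (!is_number(fs)) stop_param("fs required for numeric input")
  if (spec$band_high >= fs / 2) stop_param("band_high must be below Nyquist")
  bw <- signal::butter(spec$order, c(spec$band_low, spec$band_high) / (fs / 2),
                       type = "pass")
  filtfilt_reflect(bw$b, bw$a, x)
}

#' @export
bandpass_filter.recording <- function(x, spec = filter_spec(), fs = NULL, channels = NULL) {
  fs <- x$sampling_rate
  apply_to_channels(x, channels, function(v) bandpass_filter.numeric(v, spec, fs))
}

#' Full-wave rectification
#'
#' Elementwise absolute value; idempotent.
#'
#' @param x a [recording()] or numeric vector.
#' @param channels channels to rectify when `x` is a recording.
#' @return Same type as `x`.
#' @export
rectify <- function(x, channels = NULL) UseMethod("rectify")

#' @export
rectify.numeric <- function(x, channels = NULL) abs(x)

#' @export
rectify.recording <- function(x, channels = NULL) apply_to_channels(x, channels, abs)

#' Linear-envelope extraction
#'
#' Zero-phase Butterworth low-pass (default cutoff 5 Hz, order 4) of a
#' rectified signal, clipped at zero. The 5 Hz default tracks locomotor burst
#' modulation (step cycles near 1 Hz) while averaging out the 20-1000 Hz
#' carrier.
#'
#' @param x rectified [recording()] channels or numeric vector.
#' @param cutoff low-pass cutoff in Hz (default 5).
#' @param fs sampling rate in Hz; required for numeric input.
#' @param channels channels when `x` is a recording.
#' @param order Butterworth order (default 4).
#' @return Same type as `x`; values are nonnegative.
#' @export
envelope <- function(x, cutoff = 5, fs = NULL, channels = NULL, order = 4) {
  UseMethod("envelope")
}

#' @export
envelope.numeric <- function(x, cutoff = 5, fs = NULL, channels = NULL, order = 4) {
  if (!is_number(fs)) stop_param("fs required for numeric input")
  if (cutoff <= 0 || cutoff >= fs / 2) stop_param("cutoff must lie in (0, Nyquist)")
  lp <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pmax(0, filtfilt_reflect(lp$b, lp$a, x))
}

#' @export
envelope.recording <- function(x, cutoff = 5, fs = NULL, channels = NULL, order = 4) {
  fs <- x$sampling_rate
  apply_to_channels(x, channels, function(v) envelope.numeric(v, cutoff, fs, order = order))
}
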