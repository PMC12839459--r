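#' Stimulus-triggered epoching
#'
#' Cuts one epoch per stimulus event out of a channel, time-locked to the
#' event (for pulse trains, time zero is the first pulse of the train).
#' Epoch-relative time is reported in milliseconds; the window is half-open,
#' so a (-10, 50) ms window at 4 kHz always yields 240 samples.
#'
#' @param rec a [recording()].
#' @param channel channel label to epoch.
#' @param events event table (tibble with `time_s`, optional `current_ma`,
#'   ...); defaults to `rec$events`.
#' @param window epoch window in ms relative to the stimulus,
#'   `c(t_pre, t_post)` with `t_pre < 0 < t_post` (default `c(-10, 50)`).
#' @return A tibble with one row per sample: `epoch` (integer id in event
#'   order), `channel`, `stim_time_s`, `current_ma` (NA when events carry no
#'   current), `time_ms` (relative to the stimulus) and `value_uv`. Events
#'   whose window exceeds the trace bounds are dropped with a warning; an
#'   error is raised if all are dropped.
#' @export
extract_epochs <- function(rec, channel, events = NULL, window = c(-10, 50)) {
  stopifnot(inherits(rec, "recording"))
  if (!(window[1] < 0 && 0 < window[2])) stop_param("need t_pre < 0 < t_post (ms)")
  events <- events %||% rec$events
  if (is.null(events) || nrow(events) == 0L) stop_data("no stimulus events")
  vals <- channel_values(rec, channel)
  fs <- rec$sampling_rate
  t0 <- rec$signals$time_s[1]
  n <- length(vals)

  n_ep <- round((window[2] - window[1]) / 1000 * fs)
  rel_ms <- window[1] + (seq_len(n_ep) - 1L) / fs * 1000

  has_cur <- "current_ma" %in% names(events)
  out <- vector("list", nrow(events))
  dropped <- 0L
  for (i in seq_len(nrow(events))) {
    s <- events$time_s[i]
    i0 <- as.integer(round((s + ms_to_s(window[1]) - t0) * fs)) + 1L
    if (i0 < 1L || i0 + n_ep - 1L > n) {
      dropped <- dropped + 1L
      next
    }
    out[[i]] <- tibble(
      epoch = i, channel = channel, stim_time_s = s,
      current_ma = if (has_cur) events$current_ma[i] else NA_real_,
      time_ms = rel_ms, value_uv = vals[i0:(i0 + n_ep - 1L)]
    )
  }
  if (dropped > 0L)
    warn(sprintf("dropped %d epoch(s) whose window exceeds the trace bounds", dropped))
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0L) stop_data("all epochs fell outside the trace")
  attr(out, "sampling_rate") <- fs
  attr(out, "window_ms") <- window
  out
}

epoch_matrix <- function(epochs) {
  ids <- unique(epochs$epoch)
  m <- matrix(epochs$value_uv, ncol = length(ids))
  lens <- table(epochs$epoch)
  if (length(unique(lens)) != 1L) stop_data("epochs have mismatched windows")
  colnames(m) <- as.character(ids)
  m
}

#' Average consecutive epochs
#'
#' Pointwise arithmetic mean of the first `n` consecutive epochs (default 5,
#' the convention used for evoked-response reporting). All epochs must share
#' the same window and sampling rate.
#'
#' @param epochs epoch tibble from [extract_epochs()].
#' @param n number of consecutive epochs to average (default 5; `NULL`
#'   averages all).
#' @return A tibble `time_ms`, `value_uv` with attribute `n_avg`.
#' @export
average_epochs <- function(epochs, n = 5) {
  ids <- unique(epochs$epoch)
  if (is.null(n)) n <- length(ids)
  if (length(ids) < n) stop_data(sprintf("need >= %d epochs, have %d", n, length(ids)))
  keep <- ids[seq_len(n)]
  sub <- epochs[epochs$epoch %in% keep, ]
  lens <- tapply(sub$time_ms, sub$epoch, length)
  if (length(unique(lens)) != 1L) stop_data("epochs have mismatched windows")
  m <- matrix(sub$value_uv, ncol = n)
  out <- tibble(time_ms = sub$time_ms[seq_len(nrow(m))], value_uv = rowMeans(m))
  attr(out, "n_avg") <- n
  attr(out, "sampling_rate") <- attr(epochs, "sampling_rate")
  out
}

window_mask <- function(time_ms, window) {
  time_ms >= window[1] - 1e-9 & time_ms < window[2] - 1e-9
}

#' Maximum peak-to-peak amplitude in a window
#'
#' `max - min` of the samples falling in the half-open `response_window`
#' (ms relative to the stimulus).
#'
#' @param epoch a single-epoch or averaged-epoch tibble with `time_ms` and
#'   `value_uv`.
#' @param response_window window in ms, e.g. `c(3, 30)`.
#' @return Peak-to-peak amplitude in uV (nonnegative scalar).
#' @export
peak_to_peak <- function(epoch, response_window) {
  keep <- window_mask(epoch$time_ms, response_window)
  if (!any(keep)) stop_param("empty response window")
  v <- epoch$value_uv[keep]
  max(v) - min(v)
}

#' Response-presence criterion (A_pp > 3 x SD of noise)
#'
#' Declares a response present when the maximum peak-to-peak amplitude in the
#' response window exceeds three times the sample standard deviation of a
#' designated noise window. For peripheral EES-evoked responses (onsets at
#' 3-6 ms) the noise window defaults to the pre-stimulus interval; for
#' cortical SSEPs, whose components arrive later, the 0-5 ms post-stimulus
#' window is the conventional choice.
#'
#' Note that on a raw, unaveraged epoch the criterion is liberal: the expected
#' range of ~100 noise samples is itself close to 5 SD, so the rule is meant
#' for averaged traces and for amplitudes measured on identified peak pairs
#' (see [ssep_features()]).
#'
#' @param epochs epoch tibble ([extract_epochs()] or [average_epochs()]
#'   output); with several epochs, one result row per epoch.
#' @param noise_window,response_window disjoint windows in ms.
#' @param k SD multiple of the criterion (default 3).
#' @return A tibble with one row per epoch: `epoch`, `noise_sd_uv`,
#'   `amplitude_pp_uv`, `present`.
#' @export
detect_response <- function(epochs, noise_window = c(-10, 0),
                            response_window = c(3, 30), k = 3) {
  if (max(noise_window[1], response_window[1]) <
      min(noise_window[2], response_window[2]))
    stop_param("noise and response windows must be disjoint")
  one <- function(df, id) {
    nz <- df$value_uv[window_mask(df$time_ms, noise_window)]
    if (length(nz) < 4L) stop_data("noise window has fewer than 4 samples")
    nsd <- sd(nz)
    app <- peak_to_peak(df, response_window)
    tibble(epoch = id, noise_sd_uv = nsd, amplitude_pp_uv = app,
           present = app > k * nsd)
  }
  if ("epoch" %in% names(epochs)) {
    parts <- split(epochs[c("time_ms", "value_uv")], epochs$epoch)
    ids <- unique(epochs$epoch)
    dplyr::bind_rows(lapply(ids, function(id) one(parts[[as.character(id)]], id)))
  } else {
    one(epochs, NA_integer_)
  }
}

#' Onset latency of an evoked response
#'
#' Time from the stimulus pulse to response onset, defined as the first point
#' in the search window where the absolute deviation from the baseline mean
#' exceeds `k` baseline SDs and stays above it for at least `hold` ms. The
#' crossing time is refined by linear interpolation between the bracketing
#' samples, so latency resolution is not limited to the sample grid.
#'
#' @param epochs epoch tibble; one latency per epoch.
#' @param baseline_window baseline interval in ms (default `c(-10, 0)`,
#'   pre-stimulus).
#' @param search_window onset search interval in ms (default `c(1, 20)`).
#' @param k SD multiple (default 3).
#' @param hold sustain requirement in ms (default 0.5).
#' @return A tibble `epoch`, `latency_ms` (`NA` when no sustained crossing is
#'   found).
#' @export
onset_latency <- function(epochs, baseline_window = c(-10, 0),
                          search_window = c(1, 20), k = 3, hold = 0.5) {
  fs <- attr(epochs, "sampling_rate")
  one <- function(df, id) {
    if (is.null(fs)) fs <- 1000 / median(diff(df$time_ms))
    bl <- df$value_uv[window_mask(df$time_ms, baseline_window)]
    if (length(bl) < 2L) stop_data("baseline window too short")
    mu <- mean(bl)
    sdev <- sd(bl)
    if (sdev == 0) {
      warn("degenerate baseline (SD = 0); any deviation counts as onset")
    }
    thr <- k * sdev
    keep <- which(window_mask(df$time_ms, search_window))
    dev <- abs(df$value_uv - mu)
    above <- dev[keep] > thr
    hold_n <- max(1L, ceiling(hold / 1000 * fs))
    lat <- NA_real_
    if (any(above)) {
      r <- rle(above)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      cand <- which(r$values & r$lengths >= hold_n)
      if (length(cand)) {
        i <- keep[starts[cand[1]]]
        t_i <- df$time_ms[i]
        if (i > 1L && dev[i - 1L] <= thr && dev[i] > dev[i - 1L]) {
          frac <- (thr - dev[i - 1L]) / (dev[i] - dev[i - 1L])
          t_cross <- df$time_ms[i - 1L] + frac * (t_i - df$time_ms[i - 1L])
          lat <- max(search_window[1], t_cross)
        } else lat <- t_i
      }
    }
    tibble(epoch = id, latency_ms = lat)
  }
  if ("epoch" %in% names(epochs)) {
    parts <- split(epochs[c("time_ms", "value_uv")], epochs$epoch)
    ids <- unique(epochs$epoch)
    dplyr::bind_rows(lapply(ids, function(id) one(parts[[as.character(id)]], id)))
  } else {
    one(epochs, NA_integer_)
  }
}

local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(max = integer(), min = integer()))
  d <- diff(v)
  s <- sign(d)
  # treat flats by carrying the previous slope
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  turns <- which(diff(s) != 0) + 1L
  list(max = turns[s[turns - 1L] > 0], min = turns[s[turns - 1L] < 0])
}

#' P1/N1 features of an averaged SSEP
#'
#' Locates the P1/N1 component complex of an averaged cortical somatosensory
#' evoked potential inside a search window — the adjacent pair of local
#' extrema with the dominant swing, which for physiological SSEPs is the
#' first major positive/negative deflection — and measures its peak-to-peak
#' amplitude. The positive member of the pair is reported as P1 and the
#' negative member as N1, so an inverted montage simply swaps their roles. Before extrema are
#' located the trace is low-passed (zero phase) at `peak_bandwidth_hz`,
#' matched to the several-millisecond width of cortical components, so that
#' sample-to-sample ripple on the averaged trace does not generate spurious
#' local extrema; the zero-phase smoothing does not displace the component
#' peaks. Presence applies the `A_pp > 3 x SD` criterion to the P1-N1
#' peak-pair amplitude (the quantity actually reported for SSEPs); the noise
#' SD is measured on the unsmoothed averaged trace, since that is the noise
#' the amplitude must beat.
#'
#' @param avg_epoch averaged epoch tibble ([average_epochs()] of >= 50 sweeps
#'   by convention).
#' @param search_window component search window in ms (default `c(10, 40)`).
#' @param noise_window noise window in ms for the presence criterion
#'   (default `c(0, 5)` post-stimulus).
#' @param peak_bandwidth_hz low-pass cutoff applied before peak finding
#'   (default 150; `NULL` disables).
#' @return One-row tibble: `p1_latency_ms`, `n1_latency_ms` (N1 may precede
#'   P1 on an inverted montage), `p1n1_amplitude_uv`, `noise_sd_uv`,
#'   `present`. Latencies are `NA` and `present` is `FALSE` when no peak
#'   pair reaches `3 x noise SD`.
#' @export
ssep_features <- function(avg_epoch, search_window = c(10, 40),
                          noise_window = c(0, 5), peak_bandwidth_hz = 150) {
  vals <- avg_epoch$value_uv
  nz <- vals[window_mask(avg_epoch$time_ms, noise_window)]
  if (length(nz) < 4L) stop_data("noise window has fewer than 4 samples")
  nsd <- sd(nz)
  if (!is.null(peak_bandwidth_hz)) {
    fs <- attr(avg_epoch, "sampling_rate") %||%
      (1000 / median(diff(avg_epoch$time_ms)))
    if (peak_bandwidth_hz < fs / 2) {
      lp <- signal::butter(4, peak_bandwidth_hz / (fs / 2), type = "low")
      vals <- filtfilt_reflect(lp$b, lp$a, vals)
    }
  }
  keep <- which(window_mask(avg_epoch$time_ms, search_window))
  v <- vals[keep]
  tm <- avg_epoch$time_ms[keep]
  ex <- local_extrema(v)
  absent <- tibble(p1_latency_ms = NA_real_, n1_latency_ms = NA_real_,
                   p1n1_amplitude_uv = 0, noise_sd_uv = nsd, present = FALSE)
  if (length(ex$max) == 0L || length(ex$min) == 0L) return(absent)
  # adjacent extrema in time order; the pair with the dominant swing defines
  # the component complex (for physiological SSEPs this is the first major
  # deflection). The positive member is P1, the negative member N1 — an
  # inverted montage may put N1 first, as happens in real cortical
  # recordings.
  all_ex <- sort(c(ex$max, ex$min))
  p1 <- n1 <- NA_integer_
  if (length(all_ex) >= 2L) {
    swings <- abs(v[all_ex[-length(all_ex)]] - v[all_ex[-1L]])
    j <- which.max(swings)
    if (swings[j] > 3 * nsd) {
      i1 <- all_ex[j]; i2 <- all_ex[j + 1L]
      if (v[i1] >= v[i2]) { p1 <- i1; n1 <- i2 } else { p1 <- i2; n1 <- i1 }
    }
  }
  if (is.na(p1)) return(absent)
  amp <- v[p1] - v[n1]
  tibble(p1_latency_ms = tm[p1], n1_latency_ms = tm[n1],
         p1n1_amplitude_uv = amp, noise_sd_uv = nsd,
         present = amp > 3 * nsd)
}

#' Recruitment curve over a graded current sweep
#'
#' Groups epochs by stimulus current and measures the evoked amplitude per
#' current level, in ascending current order. By default the epochs at each
#' current are averaged pointwise first (stimulus-triggered averaging) and the
#' maximum peak-to-peak is measured on the average; this shrinks the noise
#' floor by 1/sqrt(n) and makes near-threshold responses resolvable.
#' `aggregate = "mean_pp"` instead averages the per-epoch peak-to-peak values.
#'
#' @param rec a [recording()].
#' @param channel channel label.
#' @param events event table with a `current_ma` column; defaults to
#'   `rec$events`.
#' @param window epoch window in ms (default `c(-10, 50)`).
#' @param response_window amplitude window in ms (default `c(3, 30)`).
#' @param aggregate `"mean_epoch"` (default) or `"mean_pp"`.
#' @return A tibble of class `recruitment_curve`: `current_ma` (ascending),
#'   `amplitude_pp_uv`, `n_epochs`; attributes `channel`, `noise_sd_uv` (the
#'   single-epoch pre-stimulus SD, for thresholding) and `aggregate`.
#' @export
recruitment_curve <- function(rec, channel, events = NULL, window = c(-10, 50),
                              response_window = c(3, 30),
                              aggregate = c("mean_epoch", "mean_pp")) {
  aggregate <- match.arg(aggregate)
  events <- events %||% rec$events
  if (is.null(events) || !"current_ma" %in% names(events) ||
      anyNA(events$current_ma))
    stop_data("events must carry a current for every stimulus")
  eps <- extract_epochs(rec, channel, events, window)
  pre_win <- c(window[1], 0)
  noise_sd <- {
    nz <- eps$value_uv[window_mask(eps$time_ms, pre_win)]
    sd(nz)
  }
  by_cur <- split(seq_len(nrow(eps)), eps$current_ma)
  res <- purrr::map_dfr(names(by_cur), function(cur) {
    sub <- eps[by_cur[[cur]], ]
    n_ep <- length(unique(sub$epoch))
    amp <- if (aggregate == "mean_epoch") {
      avg <- average_epochs(sub, n = n_ep)
      peak_to_peak(avg, response_window)
    } else {
      mean(purrr::map_dbl(split(sub, sub$epoch), peak_to_peak,
                          response_window = response_window))
    }
    tibble(current_ma = as.numeric(cur), amplitude_pp_uv = amp, n_epochs = n_ep)
  })
  res <- dplyr::arrange(res, .data$current_ma)
  structure(res, class = c("recruitment_curve", class(res)),
            channel = channel, noise_sd_uv = noise_sd, aggregate = aggregate)
}

#' Motor threshold from a recruitment curve
#'
#' The smallest stimulus current whose amplitude exceeds `k x noise_sd` and
#' whose successor current also exceeds it (two-consecutive rule, guarding
#' against single-level noise spikes on a fine 0.1 mA grid). The last current
#' of the sweep qualifies on its own if it exceeds the criterion.
#'
#' @param curve a [recruitment_curve()].
#' @param noise_sd single-epoch noise SD in uV (default: the value measured by
#'   [recruitment_curve()] from the pre-stimulus window).
#' @param k SD multiple (default 3).
#' @return Threshold current in mA, or `NA` if no current qualifies.
#' @export
motor_threshold <- function(curve, noise_sd = NULL, k = 3) {
  noise_sd <- noise_sd %||% attr(curve, "noise_sd_uv")
  if (!is_number(noise_sd)) stop_param("noise_sd required")
  above <- curve$amplitude_pp_uv > k * noise_sd
  n <- length(above)
  if (n == 0L || !any(above)) return(NA_real_)
  for (i in seq_len(n)) {
    if (above[i] && (i == n || above[i + 1L])) return(curve$current_ma[i])
  }
  NA_real_
}

#' Per-epoch evoked-response measurements
#'
#' Convenience workhorse combining [detect_response()] and [onset_latency()]
#' per epoch.
#'
#' @inheritParams detect_response
#' @inheritParams onset_latency
#' @return Tibble with one row per epoch: `epoch`, `current_ma` (if present),
#'   `noise_sd_uv`, `amplitude_pp_uv`, `present`, `latency_ms` (NA where the
#'   response is absent or no onset is found).
#' @export
measure_epochs <- function(epochs, noise_window = c(-10, 0),
                           response_window = c(3, 30),
                           search_window = c(1, 20), k = 3, hold = 0.5) {
  det <- detect_response(epochs, noise_window, response_window, k)
  lat <- onset_latency(epochs, noise_window, search_window, k, hold)
  out <- dplyr::left_join(det, lat, by = "epoch")
  if ("current_ma" %in% names(epochs)) {
    cur <- dplyr::distinct(epochs[, c("epoch", "current_ma")])
    out <- dplyr::left_join(cur, out, by = "epoch")
  }
  out$latency_ms[!out$present] <- NA_real_
  out
}
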