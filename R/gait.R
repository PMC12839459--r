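as_gonio_tbl <- function(g, angle_col = "angle_deg") {
  if (inherits(g, "recording")) {
    lab <- g$channels$label[g$channels$kind == "angle"]
    if (length(lab) != 1L)
      stop_data("recording must contain exactly one angle channel; name one explicitly")
    tibble(time_s = g$signals$time_s, angle_deg = g$signals[[lab]])
  } else {
    g <- as_tibble(g)
    if (!all(c("time_s", angle_col) %in% names(g)))
      stop_format(paste0("goniogram needs columns time_s and ", angle_col))
    tibble(time_s = g$time_s, angle_deg = g[[angle_col]])
  }
}

gonio_rate <- function(g) 1 / median(diff(g$time_s))

#' Step-period estimation from a goniogram
#'
#' Estimates the gait-cycle period as the lag of the first prominent peak of
#' the autocorrelation of the mean-removed joint-angle trace, searched within
#' physiological bounds (0.3-2.0 s for quadrupedal treadmill gait by default).
#'
#' @param g goniogram: tibble with `time_s` and `angle_deg` columns (or a
#'   [recording()] with a single angle channel).
#' @param search search bounds in seconds, `c(min, max)` (default
#'   `c(0.3, 2)`).
#' @param min_acf prominence floor: the autocorrelation peak must reach this
#'   value (default 0.2).
#' @return Period in seconds.
#' @export
estimate_step_period <- function(g, search = c(0.3, 2.0), min_acf = 0.2) {
  g <- as_gonio_tbl(g)
  fs <- gonio_rate(g)
  x <- g$angle_deg - mean(g$angle_deg)
  max_lag <- min(length(x) - 1L, ceiling(search[2] * fs) + 2L)
  if (sd(x) == 0)
    stop_data("constant trace: no autocorrelation peak; supply a manual period")
  ac <- as.numeric(acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE)$acf)
  if (!all(is.finite(ac)))
    stop_data("degenerate autocorrelation; supply a manual period")
  lags <- seq_along(ac) - 1L
  in_search <- lags / fs >= search[1] & lags / fs <= search[2]
  idx <- which(in_search)
  if (length(idx) < 3L) stop_data("search bounds leave too few lags")
  # local maxima of the acf inside the search band, above the prominence floor
  is_peak <- ac[idx] >= min_acf &
    ac[pmax(idx - 1L, 1L)] <= ac[idx] &
    ac[pmin(idx + 1L, length(ac))] <= ac[idx]
  peaks <- idx[is_peak]
  if (length(peaks) == 0L)
    stop_data("no autocorrelation peak above the prominence floor; supply a manual period")
  lag0 <- peaks[1] - 1L
  # parabolic refinement around the discrete peak
  if (lag0 >= 1L && lag0 + 2L <= length(ac)) {
    y1 <- ac[lag0]; y2 <- ac[lag0 + 1L]; y3 <- ac[lag0 + 2L]
    denom <- (y1 - 2 * y2 + y3)
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    return((lag0 + delta) / fs)
  }
  lag0 / fs
}

#' Tile a goniogram into fixed-length analysis windows
#'
#' Consecutive, non-overlapping windows of length `factor * period`
#' (1.5 step cycles by default) tiling the recording from its start; a final
#' partial window is dropped.
#'
#' @param g goniogram tibble (or recording with one angle channel).
#' @param period step period in seconds.
#' @param factor window length in step periods (default 1.5).
#' @return Tibble `window`, `start_s`, `stop_s` (half-open windows).
#' @export
segment_windows <- function(g, period, factor = 1.5) {
  g <- as_gonio_tbl(g)
  if (!is_number(period) || period <= 0) stop_param("period must be > 0")
  len <- factor * period
  t0 <- g$time_s[1]
  span <- g$time_s[nrow(g)] - t0 + 1 / gonio_rate(g)
  n_win <- floor(span / len + 1e-9)
  if (n_win < 1L) stop_data("analysis window is longer than the recording")
  tibble(window = seq_len(n_win),
         start_s = t0 + (seq_len(n_win) - 1) * len,
         stop_s = t0 + seq_len(n_win) * len)
}

#' Range of motion within one window
#'
#' Maximum minus minimum joint angle over a half-open time window — the
#' per-interval "volume of angular movement".
#'
#' @param g goniogram tibble (or recording with one angle channel).
#' @param window `c(start_s, stop_s)` in seconds.
#' @return Range of motion in degrees (nonnegative scalar).
#' @export
rom_per_window <- function(g, window) {
  g <- as_gonio_tbl(g)
  sub <- slice_window(g, window[1], window[2])
  max(sub$angle_deg) - min(sub$angle_deg)
}

#' Session range-of-motion summary
#'
#' Runs the full kinematic chain on the first `duration` seconds of a
#' goniogram: [estimate_step_period()], [segment_windows()] with 1.5-cycle
#' windows, [rom_per_window()] per window, then mean, median and IQR over
#' windows (the per-session summary reported for treadmill locomotion).
#'
#' An optional moving average over `smooth_frames` frames is applied before
#' the extrema are taken; marker-tracking jitter inflates max-min range, and
#' smoothing over roughly 0.1 s (5 frames at 50 Hz) suppresses most of that
#' positive bias at negligible cost in true amplitude. The default (0) leaves
#' the trace untouched.
#'
#' @param g goniogram tibble with `time_s`, `angle_deg` (or recording with a
#'   single angle channel).
#' @param duration analysis duration in seconds from the start of the trace
#'   (default 60).
#' @param factor window length in step periods (default 1.5).
#' @param period optional manual step period in seconds (skips
#'   [estimate_step_period()]).
#' @param smooth_frames moving-average length in frames applied before
#'   extrema; 0 disables (default).
#' @param search,min_acf passed to [estimate_step_period()].
#' @return Object of class `rom_summary`: list with `per_window` (tibble
#'   `window`, `start_s`, `stop_s`, `rom_deg`), `mean_rom`, `median_rom`,
#'   `q1`, `q3`, `iqr`, `n_windows`, `window_length`, `period`.
#' @export
summarize_rom <- function(g, duration = 60, factor = 1.5, period = NULL,
                          smooth_frames = 0, search = c(0.3, 2.0),
                          min_acf = 0.2) {
  g <- as_gonio_tbl(g)
  t0 <- g$time_s[1]
  g <- g[g$time_s < t0 + duration - 1e-9, ]
  if (is.null(period)) period <- estimate_step_period(g, search, min_acf)
  if (smooth_frames >= 2) {
    k <- as.integer(smooth_frames)
    sm <- stats::filter(g$angle_deg, rep(1 / k, k), sides = 2)
    keep <- !is.na(sm)
    g <- tibble(time_s = g$time_s[keep], angle_deg = as.numeric(sm[keep]))
  }
  wins <- segment_windows(g, period, factor)
  if (nrow(wins) < 2L) stop_data("fewer than 2 analysis windows; trace too short")
  roms <- purrr::map_dbl(seq_len(nrow(wins)), function(i)
    rom_per_window(g, c(wins$start_s[i], wins$stop_s[i])))
  q <- quartiles(roms)
  structure(
    list(per_window = dplyr::mutate(wins, rom_deg = roms),
         mean_rom = mean(roms), median_rom = median(roms),
         q1 = q[["q1"]], q3 = q[["q3"]], iqr = q[["q3"]] - q[["q1"]],
         n_windows = nrow(wins), window_length = factor * period,
         period = period, smooth_frames = smooth_frames),
    class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  cat(sprintf(
    "<rom_summary> %d windows of %.3f s (period %.3f s)\n  mean ROM %.2f deg, median %.2f deg [IQR %.2f, %.2f]\n",
    x$n_windows, x$window_length, x$period, x$mean_rom, x$median_rom, x$q1, x$q3))
  invisible(x)
}
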