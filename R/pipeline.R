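#' Evoked-response analysis settings
#'
#' Window and criterion settings for [run_evoked_pipeline()], serialisable to
#' the pipeline JSON report. All epoch-relative windows are in ms.
#'
#' @param epoch_window epoch span `c(t_pre, t_post)` (default `c(-10, 50)`).
#' @param noise_window noise window for the presence criterion; the default
#'   pre-stimulus interval suits peripheral EES-evoked responses whose onsets
#'   fall at 3-6 ms. Use `c(0, 5)` post-stimulus for cortical SSEPs.
#' @param response_window amplitude window (default `c(3, 30)`).
#' @param search_window onset search window (default `c(1, 20)`).
#' @param k SD multiple of the presence/onset criterion (default 3).
#' @param hold onset sustain requirement in ms (default 0.5).
#' @param n_avg epochs averaged per reported value (default 5 consecutive
#'   stimuli).
#' @param filters a [filter_spec()].
#' @return List of class `evoked_settings`.
#' @export
evoked_settings <- function(epoch_window = c(-10, 50), noise_window = c(-10, 0),
                            response_window = c(3, 30), search_window = c(1, 20),
                            k = 3, hold = 0.5, n_avg = 5,
                            filters = filter_spec()) {
  structure(as.list(environment()), class = "evoked_settings")
}

#' End-to-end evoked-response pipeline
#'
#' Chains the full evoked analysis per channel: conditioning (band-pass +
#' notch), stimulus-triggered epoching, per-current grouping, presence
#' criterion and amplitude on the per-current averaged epoch, per-epoch onset
#' latencies averaged over `n_avg` consecutive stimuli, and (when the sweep
#' covers at least two currents) a recruitment curve and motor threshold.
#'
#' @param rec a [recording()] with stimulus events.
#' @param channels channels to analyse (default: all EMG channels).
#' @param settings an [evoked_settings()].
#' @param out_dir optional directory; when given, tidy CSVs
#'   (`evoked_responses.csv`, `thresholds.csv`) and a JSON report
#'   (`report.json`) are written with fixed 6-significant-digit number
#'   formatting.
#' @return List with `responses` (tibble: one row per channel x current:
#'   `channel`, `current_ma`, `n_epochs`, `noise_sd_uv`, `amplitude_pp_uv`,
#'   `present`, `latency_ms` = mean of per-epoch latencies over the first
#'   `n_avg` epochs, `latency_avg_epoch_ms` = latency measured on the
#'   averaged epoch) and `thresholds` (tibble: `channel`, `threshold_ma`,
#'   `noise_sd_uv`).
#' @export
run_evoked_pipeline <- function(rec, channels = NULL,
                                settings = evoked_settings(), out_dir = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(rec$events) || nrow(rec$events) == 0L) stop_data("recording has no events")
  channels <- channels %||% rec$channels$label[rec$channels$kind == "emg"]
  s <- settings
  rec_f <- notch_filter(bandpass_filter(rec, s$filters, channels = channels),
                        s$filters, channels = channels)

  responses <- list()
  thresholds <- list()
  for (ch in channels) {
    eps <- extract_epochs(rec_f, ch, window = s$epoch_window)
    has_cur <- "current_ma" %in% names(rec$events)
    cur_of <- if (has_cur) eps$current_ma else rep(NA_real_, nrow(eps))
    grp_key <- ifelse(is.na(cur_of), "all", format(cur_of, trim = TRUE))
    groups <- split(seq_len(nrow(eps)),
                    factor(grp_key, levels = unique(grp_key[order(cur_of)])))
    for (g in names(groups)) {
      sub <- eps[groups[[g]], ]
      attr(sub, "sampling_rate") <- attr(eps, "sampling_rate")
      ids <- unique(sub$epoch)
      avg <- average_epochs(sub, n = length(ids))
      attr(avg, "sampling_rate") <- attr(eps, "sampling_rate")
      det <- detect_response(avg, s$noise_window, s$response_window, s$k)
      per_ep <- measure_epochs(sub, s$noise_window, s$response_window,
                               s$search_window, s$k, s$hold)
      lat_first <- per_ep$latency_ms[seq_len(min(s$n_avg, nrow(per_ep)))]
      lat_mean <- if (all(is.na(lat_first))) NA_real_ else mean(lat_first, na.rm = TRUE)
      lat_avg <- onset_latency(avg, s$noise_window, s$search_window,
                               s$k, s$hold)$latency_ms
      responses[[length(responses) + 1L]] <- tibble(
        channel = ch, current_ma = suppressWarnings(as.numeric(g)),
        n_epochs = length(ids), noise_sd_uv = det$noise_sd_uv,
        amplitude_pp_uv = det$amplitude_pp_uv, present = det$present,
        latency_ms = lat_mean, latency_avg_epoch_ms = lat_avg)
    }
    if (has_cur && length(unique(rec$events$current_ma)) >= 2L) {
      curve <- recruitment_curve(rec_f, ch, window = s$epoch_window,
                                 response_window = s$response_window)
      thresholds[[length(thresholds) + 1L]] <- tibble(
        channel = ch, threshold_ma = motor_threshold(curve, k = s$k),
        noise_sd_uv = attr(curve, "noise_sd_uv"))
    }
  }
  out <- list(responses = dplyr::bind_rows(responses),
              thresholds = if (length(thresholds)) dplyr::bind_rows(thresholds)
                           else tibble(channel = character(),
                                       threshold_ma = numeric(),
                                       noise_sd_uv = numeric()))
  if (!is.null(out_dir)) write_report(out, out_dir, settings = s,
                                      files = c(responses = "evoked_responses.csv",
                                                thresholds = "thresholds.csv"))
  out
}

#' End-to-end gait pipeline: ROM summaries and coactivation
#'
#' Range-of-motion summaries per joint, side and condition from long-format
#' goniogram data, plus (optionally) antagonist coactivation from a locomotor
#' EMG recording.
#'
#' @param gonio long tibble with columns `time_s`, `angle_deg`, `joint`,
#'   `side`, `condition` (grouping columns may be omitted if constant).
#' @param emg_rec optional [recording()] for [coactivation_table()].
#' @param pairs antagonist pairing table (default [antagonist_pairs()]).
#' @param duration,factor,smooth_frames passed to [summarize_rom()].
#' @param out_dir optional output directory for tidy CSVs
#'   (`rom_summary.csv`, `coactivation.csv`) and `report.json`.
#' @return List with `rom` (tibble: `joint`, `side`, `condition`,
#'   `mean_rom_deg`, `median_rom_deg`, `q1_deg`, `q3_deg`, `iqr_deg`,
#'   `n_windows`, `period_s`) and `coactivation` (tibble or `NULL`).
#' @export
run_gait_pipeline <- function(gonio, emg_rec = NULL, pairs = antagonist_pairs(),
                              duration = 60, factor = 1.5, smooth_frames = 0,
                              out_dir = NULL) {
  gonio <- as_tibble(gonio)
  for (col in c("joint", "side", "condition"))
    if (!col %in% names(gonio)) gonio[[col]] <- "unspecified"
  rom <- gonio |>
    dplyr::group_by(.data$joint, .data$side, .data$condition) |>
    dplyr::group_modify(function(df, key) {
      rs <- summarize_rom(df, duration = duration, factor = factor,
                          smooth_frames = smooth_frames)
      tibble(mean_rom_deg = rs$mean_rom, median_rom_deg = rs$median_rom,
             q1_deg = rs$q1, q3_deg = rs$q3, iqr_deg = rs$iqr,
             n_windows = rs$n_windows, period_s = rs$period)
    }) |>
    dplyr::ungroup()
  coact <- if (!is.null(emg_rec)) coactivation_table(emg_rec, pairs)
  out <- list(rom = rom, coactivation = coact)
  if (!is.null(out_dir)) write_report(out, out_dir,
                                      files = c(rom = "rom_summary.csv",
                                                coactivation = "coactivation.csv"))
  out
}

# tidy CSV + JSON report emission with byte-stable number formatting
write_report <- function(results, out_dir, settings = NULL, files) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(files)) {
    df <- results[[nm]]
    if (is.null(df)) next
    df_fmt <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), format_num))
    readr::write_csv(df_fmt, file.path(out_dir, files[[nm]]), progress = FALSE)
  }
  report <- list(
    generated_by = paste0("neuromotor ", as.character(utils::packageVersion("neuromotor"))),
    tables = as.list(files[!vapply(results[names(files)], is.null, logical(1))]),
    settings = if (!is.null(settings)) unclass(settings))
  if (!is.null(report$settings$filters))
    report$settings$filters <- unclass(report$settings$filters)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
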