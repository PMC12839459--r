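#' Multichannel uniformly sampled recording
#'
#' A `recording` bundles the unit of I/O used throughout the package: a wide
#' signals table (one `time_s` column plus one column per channel), per-channel
#' metadata (kind and units), an optional stimulus-event table, and session
#' metadata. Sampling is uniform; the rate is inferred from the time column and
#' checked to be uniform within a relative tolerance of `1e-6`.
#'
#' Channel naming follows the `<MUSCLE>_<SIDE>` convention (for example `TA_R`,
#' `GM_L`); EMG channels are in microvolts, joint-angle channels in degrees.
#'
#' @param signals data frame with a `time_s` column (seconds, strictly
#'   increasing, uniformly spaced) and one numeric column per channel.
#' @param channels data frame describing each channel with columns `label`,
#'   `kind` (one of `"emg"`, `"angle"`, `"neural"`) and `units` (`"uV"` or
#'   `"deg"`). If `NULL`, every non-time column is assumed to be EMG in uV.
#' @param events optional data frame of stimulus events with column `time_s`
#'   (seconds, strictly increasing) and optional columns `current_ma`,
#'   `pulse_width_us`, `train_pulses`, `isi_ms`, `label`.
#' @param meta named list of session metadata; recognised keys are
#'   `animal_id`, `session_id`, `condition` (`"pre_SCI"` or `"post_SCI"`),
#'   `ees_state` (`"off"` or `"on"`) and `notes`.
#' @return An object of class `recording`: a list with elements `signals`
#'   (tibble), `channels` (tibble), `events` (tibble or `NULL`), `meta` (list)
#'   and `sampling_rate` (Hz).
#' @examples
#' t <- seq(0, 1, by = 1 / 4000)[1:4000]
#' rec <- recording(data.frame(time_s = t, TA_R = sin(2 * pi * 10 * t)))
#' rec$sampling_rate
#' @export
recording <- function(signals, channels = NULL, events = NULL, meta = list()) {
  signals <- as_tibble(signals)
  if (!"time_s" %in% names(signals)) stop_format("signals must contain a 'time_s' column")
  ch_labels <- setdiff(names(signals), "time_s")
  if (length(ch_labels) == 0L) stop_format("recording has no channels")
  if (anyDuplicated(ch_labels)) stop_format("duplicated channel labels in signals")

  tt <- signals$time_s
  if (length(tt) < 2L) stop_format("need at least two samples")
  dt <- diff(tt)
  if (any(dt <= 0)) stop_format("time_s column is not strictly increasing")
  dt0 <- median(dt)
  if (max(abs(dt - dt0)) > 1e-6 * dt0 + 1e-12)
    stop_format("non-uniform sampling in time_s beyond relative tolerance 1e-6")
  fs <- 1 / dt0

  if (is.null(channels)) {
    channels <- tibble(label = ch_labels, kind = "emg", units = "uV")
  } else {
    channels <- as_tibble(channels)
    if (!all(c("label", "kind", "units") %in% names(channels)))
      stop_config("channels table needs columns label, kind, units")
    if (!setequal(channels$label, ch_labels))
      stop_config("channel metadata labels do not match signal columns")
    channels <- channels[match(ch_labels, channels$label), ]
  }
  bad <- !channels$kind %in% c("emg", "angle", "neural")
  if (any(bad)) stop_config(paste0("unknown channel kind for: ",
                                   paste(channels$label[bad], collapse = ", ")))

  if (!is.null(events)) {
    events <- as_tibble(events)
    if (!"time_s" %in% names(events)) stop_format("events must contain a 'time_s' column")
    if (nrow(events) > 1L && any(diff(events$time_s) <= 0))
      stop_format("event times must be strictly increasing")
    if ("current_ma" %in% names(events) &&
        any(events$current_ma < 0, na.rm = TRUE))
      stop_format("event currents must be >= 0")
    if ("train_pulses" %in% names(events) &&
        any(events$train_pulses < 1, na.rm = TRUE))
      stop_format("train_pulses must be >= 1")
  }

  structure(
    list(signals = signals, channels = channels, events = events,
         meta = meta, sampling_rate = fs),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %d samples @ %.6g Hz, %.3f-%.3f s\n",
              nrow(x$channels), nrow(x$signals), x$sampling_rate,
              min(x$signals$time_s), max(x$signals$time_s)))
  cat("  channels:", paste0(x$channels$label, " (", x$channels$kind, ")",
                            collapse = ", "), "\n")
  if (!is.null(x$events)) cat(sprintf("  events: %d\n", nrow(x$events)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

required_meta_keys <- c("animal_id", "session_id", "condition", "ees_state")

#' Read a recording from CSV + JSON sidecar
#'
#' Reads the interchange format written by [write_recording()]: a wide signals
#' CSV (`time_s` plus one column per channel), a JSON metadata sidecar
#' (`<stem>.json`) carrying session metadata and per-channel kind/units, and an
#' optional events CSV (`<stem>_events.csv`).
#'
#' @param path path to the signals CSV.
#' @param require_meta should missing session-metadata keys raise an error
#'   (default `TRUE`)? The required keys are `animal_id`, `session_id`,
#'   `condition`, `ees_state`.
#' @return A validated [recording()].
#' @export
read_recording <- function(path, require_meta = TRUE) {
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  sig <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (anyDuplicated(names(sig))) stop_format("duplicated channel header in signals CSV")

  stem <- sub("\\.csv$", "", path)
  meta_path <- paste0(stem, ".json")
  events_path <- paste0(stem, "_events.csv")

  channels <- NULL
  meta <- list()
  if (file.exists(meta_path)) {
    js <- jsonlite::read_json(meta_path, simplifyVector = FALSE)
    meta <- js[setdiff(names(js), "channels")]
    if (!is.null(js$channels)) {
      channels <- purrr::imap_dfr(js$channels, function(ch, lab)
        tibble(label = lab, kind = ch$kind %||% "emg", units = ch$units %||% "uV"))
    }
    missing <- setdiff(required_meta_keys, names(meta))
    if (require_meta && length(missing))
      stop_config(paste("missing required metadata keys:",
                        paste(missing, collapse = ", ")))
  } else if (require_meta) {
    stop_config(paste("missing metadata sidecar:", meta_path))
  }

  events <- NULL
  if (file.exists(events_path))
    events <- readr::read_csv(events_path, show_col_types = FALSE, progress = FALSE)

  recording(sig, channels = channels, events = events, meta = meta)
}

#' Write a recording to CSV + JSON sidecar
#'
#' Emits the same dialect [read_recording()] accepts: signals CSV with
#' `time_s` first and channels in lexicographic order, a JSON metadata sidecar,
#' and an events CSV when events are present. All numbers use `.` as decimal
#' separator and no thousands separator; values are written with enough digits
#' for a lossless round trip at double precision.
#'
#' @param rec a [recording()].
#' @param path path for the signals CSV; the sidecars derive from its stem.
#' @return Invisibly, the paths written.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ch <- sort(setdiff(names(rec$signals), "time_s"))
  if (length(ch) == 0L) stop_data("recording has no channels; nothing to write")
  sig <- rec$signals[, c("time_s", ch)]

  stem <- sub("\\.csv$", "", path)
  meta_path <- paste0(stem, ".json")
  events_path <- paste0(stem, "_events.csv")

  readr::write_csv(sig, path, progress = FALSE)
  chmeta <- lapply(seq_len(nrow(rec$channels)), function(i)
    list(kind = rec$channels$kind[i], units = rec$channels$units[i]))
  names(chmeta) <- rec$channels$label
  js <- c(rec$meta, list(channels = chmeta[ch]))
  jsonlite::write_json(js, meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  written <- c(path, meta_path)
  if (!is.null(rec$events) && nrow(rec$events)) {
    readr::write_csv(rec$events, events_path, progress = FALSE)
    written <- c(written, events_path)
  }
  invisible(written)
}

#' Slice a half-open time window out of a trace or recording
#'
#' Selects samples with `start <= time_s < stop` (half-open convention, so
#' adjacent windows never double-count a boundary sample).
#'
#' @param x a [recording()] or a data frame with a `time_s` column.
#' @param start,stop window bounds in seconds, `start < stop`.
#' @return Same type as `x`, restricted to the window. For recordings, events
#'   outside the window are dropped.
#' @export
slice_window <- function(x, start, stop) {
  if (!is_number(start) || !is_number(stop) || start >= stop)
    stop_param("need start < stop")
  UseMethod("slice_window")
}

#' @export
slice_window.data.frame <- function(x, start, stop) {
  eps <- 1e-9 * max(1, abs(start), abs(stop))
  out <- x[x$time_s >= start - eps & x$time_s < stop - eps, , drop = FALSE]
  if (nrow(out) == 0L) stop_param("window does not intersect the trace")
  as_tibble(out)
}

#' @export
slice_window.recording <- function(x, start, stop) {
  sig <- slice_window.data.frame(x$signals, start, stop)
  ev <- x$events
  if (!is.null(ev)) ev <- ev[ev$time_s >= start & ev$time_s < stop, , drop = FALSE]
  recording(sig, channels = x$channels, events = if (!is.null(ev) && nrow(ev)) ev,
            meta = x$meta)
}

#' Check recording invariants
#'
#' Reports (rather than throws) violations of the recording invariants: finite
#' samples, positive sampling rate, unit/kind consistency (EMG and neural
#' channels in uV, angle channels in degrees), and all event times inside the
#' channel time span.
#'
#' @param rec a [recording()].
#' @return A tibble with columns `field` and `message`; zero rows when the
#'   recording is valid.
#' @export
validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  v <- list()
  add <- function(field, message) v[[length(v) + 1L]] <<- tibble(field = field, message = message)

  if (!is_number(rec$sampling_rate) || rec$sampling_rate <= 0)
    add("sampling_rate", "sampling rate must be positive and finite")
  for (lab in rec$channels$label) {
    vals <- rec$signals[[lab]]
    if (!all(is.finite(vals)))
      add(lab, sprintf("channel '%s' contains %d non-finite sample(s)",
                       lab, sum(!is.finite(vals))))
    kind <- rec$channels$kind[rec$channels$label == lab]
    units <- rec$channels$units[rec$channels$label == lab]
    ok_units <- (kind %in% c("emg", "neural") && units == "uV") ||
      (kind == "angle" && units == "deg")
    if (!ok_units)
      add(lab, sprintf("channel '%s': units '%s' inconsistent with kind '%s'",
                       lab, units, kind))
  }
  if (!is.null(rec$events) && nrow(rec$events)) {
    span <- range(rec$signals$time_s)
    out <- rec$events$time_s < span[1] | rec$events$time_s > span[2]
    if (any(out))
      add("events", sprintf("%d event(s) outside the trace span [%.6g, %.6g] s",
                            sum(out), span[1], span[2]))
  }
  if (length(rec$meta)) {
    if (!is.null(rec$meta$condition) &&
        !rec$meta$condition %in% c("pre_SCI", "post_SCI"))
      add("meta", "condition must be 'pre_SCI' or 'post_SCI'")
    if (!is.null(rec$meta$ees_state) && !rec$meta$ees_state %in% c("off", "on"))
      add("meta", "ees_state must be 'off' or 'on'")
  }
  if (length(v)) dplyr::bind_rows(v) else tibble(field = character(), message = character())
}

# pull one channel as a numeric vector, with its sampling rate
channel_values <- function(rec, channel) {
  if (!channel %in% rec$channels$label)
    stop_data(paste0("no such channel: '", channel, "'"))
  rec$signals[[channel]]
}
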