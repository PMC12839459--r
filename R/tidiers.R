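#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot aes ggplot geom_line geom_point geom_hline
#'   geom_col geom_errorbar labs theme_minimal coord_equal geom_vline
#' @export
ggplot2::autoplot

#' @describeIn summarize_rom per-window ROM values as a tibble.
#' @param x a `rom_summary` object.
#' @param ... unused.
#' @export
tidy.rom_summary <- function(x, ...) x$per_window

#' @describeIn summarize_rom one-row session summary.
#' @export
glance.rom_summary <- function(x, ...) {
  tibble(mean_rom_deg = x$mean_rom, median_rom_deg = x$median_rom,
         q1_deg = x$q1, q3_deg = x$q3, iqr_deg = x$iqr,
         n_windows = x$n_windows, window_length_s = x$window_length,
         period_s = x$period)
}

#' @describeIn coordination_profile activation scatter points as a tibble.
#' @param x a `coordination_profile`.
#' @param ... unused.
#' @export
tidy.coordination_profile <- function(x, ...) x$points

#' @describeIn coordination_profile one-row summary with the L-shape score.
#' @export
glance.coordination_profile <- function(x, ...) {
  tibble(pair_a = x$pair[1], pair_b = x$pair[2],
         l_shape_score = x$l_shape_score, n_samples = x$n_samples)
}

#' @describeIn recruitment_curve curve points with the estimated threshold
#'   marked.
#' @param x a `recruitment_curve`.
#' @param ... unused.
#' @export
glance.recruitment_curve <- function(x, ...) {
  thr <- motor_threshold(x)
  tibble(channel = attr(x, "channel"), threshold_ma = thr,
         noise_sd_uv = attr(x, "noise_sd_uv"), n_currents = nrow(x))
}

#' Plot a recruitment curve
#'
#' Amplitude versus stimulus current with the 3xSD criterion line and the
#' estimated motor threshold.
#'
#' @param object a [recruitment_curve()].
#' @param k SD multiple drawn as the criterion line (default 3).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.recruitment_curve <- function(object, k = 3, ...) {
  thr <- motor_threshold(object, k = k)
  p <- ggplot(object, aes(x = .data$current_ma, y = .data$amplitude_pp_uv)) +
    geom_line(colour = "grey40") + geom_point() +
    geom_hline(yintercept = k * attr(object, "noise_sd_uv"), linetype = 2) +
    labs(x = "Stimulus current (mA)", y = "Peak-to-peak amplitude (uV)",
         title = paste0("Recruitment curve: ", attr(object, "channel"))) +
    theme_minimal()
  if (!is.na(thr)) p <- p + geom_vline(xintercept = thr, colour = "red3",
                                       linetype = 3)
  p
}

#' Plot per-window range of motion
#'
#' @param object a `rom_summary` from [summarize_rom()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.rom_summary <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$start_s, y = .data$rom_deg)) +
    geom_col(fill = "steelblue", width = 0.8 * object$window_length) +
    geom_hline(yintercept = object$mean_rom, linetype = 2) +
    labs(x = "Time (s)", y = "Range of motion (deg)",
         title = sprintf("Per-window ROM (mean %.1f deg)", object$mean_rom)) +
    theme_minimal()
}

#' Plot the L-shaped coordination scatter
#'
#' @param object a [coordination_profile()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.coordination_profile <- function(object, ...) {
  ggplot(object$points, aes(x = .data$a, y = .data$b)) +
    geom_point(alpha = 0.4, size = 0.8) +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = paste(object$pair[1], "activation"),
         y = paste(object$pair[2], "activation"),
         title = sprintf("Coordination profile (L-shape score %.2f)",
                         object$l_shape_score)) +
    theme_minimal()
}

#' Plot epochs with their average
#'
#' Butterfly plot of stimulus-locked epochs with the pointwise average
#' overlaid.
#'
#' @param epochs epoch tibble from [extract_epochs()].
#' @param n_avg epochs entering the overlaid average (default all).
#' @return A ggplot object.
#' @export
plot_epochs <- function(epochs, n_avg = NULL) {
  avg <- average_epochs(epochs, n = n_avg %||% length(unique(epochs$epoch)))
  ggplot(epochs, aes(x = .data$time_ms, y = .data$value_uv,
                     group = .data$epoch)) +
    geom_line(alpha = 0.3, linewidth = 0.3) +
    geom_line(data = avg, aes(group = NULL), colour = "red3", linewidth = 0.7) +
    geom_vline(xintercept = 0, linetype = 3) +
    labs(x = "Time from stimulus (ms)", y = "Amplitude (uV)") +
    theme_minimal()
}
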