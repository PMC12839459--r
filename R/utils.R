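#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom stats sd median quantile acf shapiro.test t.test plogis qlogis rnorm
NULL

stop_format <- function(msg) abort(msg, class = "neuromotor_format_error")
stop_config <- function(msg) abort(msg, class = "neuromotor_config_error")
stop_param  <- function(msg) abort(msg, class = "neuromotor_parameter_error")
stop_data   <- function(msg) abort(msg, class = "neuromotor_data_error")

# milliseconds <-> seconds; all absolute time is seconds, epoch-relative time
# and latencies are milliseconds
ms_to_s <- function(x) x / 1000
s_to_ms <- function(x) x * 1000

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Quartiles by linear interpolation
#'
#' Type-7 (linear interpolation) quartiles, the convention used for all
#' interquartile-range summaries in this package.
#'
#' @param x numeric vector.
#' @return named numeric vector `c(q1, q3)`.
#' @keywords internal
quartiles <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.75), type = 7, names = FALSE))
  c(q1 = q[1], q3 = q[2])
}

format_num <- function(x) {
  # fixed 6-significant-digit formatting so emitted CSVs are byte-stable
  ifelse(is.na(x), NA_character_, formatC(signif(x, 6), format = "g", digits = 6))
}
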