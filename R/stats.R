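#' Descriptive group summary
#'
#' The summary scheme used for reporting: mean with standard error of the
#' mean (sample SD / sqrt(n)), median with linear-interpolation (type-7)
#' quartiles, and a Shapiro-Wilk normality p-value (defined for n >= 3;
#' `NA` for constant samples, where the test is undefined).
#'
#' @param values numeric vector, n >= 1.
#' @return One-row tibble: `n`, `mean`, `sem`, `median`, `q1`, `q3`, `iqr`,
#'   `normality_p`.
#' @export
group_summary <- function(values) {
  if (length(values) == 0L) stop_data("empty input")
  n <- length(values)
  sem <- if (n > 1L) sd(values) / sqrt(n) else NA_real_
  q <- if (n > 1L) quartiles(values) else c(q1 = values, q3 = values)
  normality_p <- if (n >= 3L && sd(values) > 0) {
    tryCatch(shapiro.test(values)$p.value, error = function(e) NA_real_)
  } else NA_real_
  tibble(n = n, mean = mean(values), sem = sem, median = median(values),
         q1 = unname(q["q1"]), q3 = unname(q["q3"]),
         iqr = unname(q["q3"] - q["q1"]), normality_p = normality_p)
}

#' Paired-samples comparison
#'
#' Two-sided paired t-test between matched conditions, with significance at
#' alpha = 0.05. Zero-variance differences are degenerate for the t
#' statistic and are handled by convention: identical samples give p = 1, a
#' constant nonzero shift gives p = 0 (certainty), both flagged
#' `degenerate = TRUE` with a warning.
#'
#' @param pre,post equal-length numeric vectors of paired measurements,
#'   n >= 2.
#' @param alpha significance level (default 0.05).
#' @return One-row tibble of class `paired_comparison`: `n_pairs`,
#'   `statistic`, `p_value`, `method`, `significant`, `degenerate`.
#' @export
paired_comparison <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post)) stop_data("pre and post must have equal length")
  n <- length(pre)
  if (n < 2L) stop_data("need at least 2 pairs")
  d <- post - pre
  if (sd(d) == 0) {
    if (all(d == 0)) {
      warn("all differences are zero; degenerate comparison, p = 1 by convention")
      out <- tibble(n_pairs = n, statistic = NA_real_, p_value = 1,
                    method = "paired_t", significant = FALSE, degenerate = TRUE)
    } else {
      warn("zero-variance nonzero shift; degenerate certainty, p = 0 by convention")
      out <- tibble(n_pairs = n, statistic = sign(mean(d)) * Inf, p_value = 0,
                    method = "paired_t", significant = TRUE, degenerate = TRUE)
    }
  } else {
    tt <- t.test(post, pre, paired = TRUE)
    out <- tibble(n_pairs = n, statistic = unname(tt$statistic),
                  p_value = tt$p.value, method = "paired_t",
                  significant = tt$p.value < alpha, degenerate = FALSE)
  }
  structure(out, class = c("paired_comparison", class(tibble())))
}
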