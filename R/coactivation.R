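#' Normalize an activation envelope
#'
#' Makes an EMG envelope amplitude-scale-free so muscles with different
#' absolute signal levels can be compared: a resting-baseline estimate (the
#' `baseline_quantile`, default 5th percentile) is subtracted, the result is
#' divided by the `ref_quantile` (default 99th percentile, robust to isolated
#' spikes), and clipped to `[0, 1]`. The baseline subtraction removes the
#' rectified-noise floor (mean `sigma * sqrt(2/pi)` of the baseline noise),
#' which would otherwise enter every sample of the coactivation numerator.
#' The output is invariant under input scaling by any positive constant.
#'
#' @param env nonnegative numeric envelope with positive maximum.
#' @param ref_quantile quantile used as the normalization reference
#'   (default 0.99).
#' @param baseline_quantile quantile used as the resting-baseline estimate
#'   (default 0.05); set to `NULL` or 0 to disable baseline subtraction.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_envelope <- function(env, ref_quantile = 0.99, baseline_quantile = 0.05) {
  if (any(env < 0)) stop_param("envelope must be nonnegative (rectify first)")
  base <- if (is.null(baseline_quantile) || baseline_quantile <= 0) 0
          else unname(quantile(env, baseline_quantile, type = 7))
  ref <- unname(quantile(env, ref_quantile, type = 7))
  if (ref - base <= 0) stop_data("degenerate envelope: normalization reference is zero")
  pmin(1, pmax(0, (env - base) / (ref - base)))
}

#' Antagonist coactivation (Rudolf) coefficient
#'
#' A bounded `[0, 1]` index of antagonist-muscle co-activity over a pair of
#' normalized activation envelopes. The default definition is
#' `sum(min(a_i, b_i)) / sum(max(a_i, b_i))`: exactly 0 for strictly
#' reciprocal activity (disjoint supports), exactly 1 for identical
#' envelopes, symmetric in its arguments, and monotone in burst overlap.
#' `method = "rudolph"` selects the classical coactivation index
#' `mean((lower_i / higher_i) * (lower_i + higher_i)) / mean(a_i + b_i)`
#' normalised to `[0, 1]` bounds.
#'
#' @param env_a,env_b equal-length normalized envelopes (see
#'   [normalize_envelope()]).
#' @param pair optional channel-label pair `c(a, b)` for labelling.
#' @param method `"min_max"` (default) or `"rudolph"`.
#' @return One-row tibble of class `coactivation_result`: `pair_a`, `pair_b`,
#'   `coefficient`, `n_samples`, `normalization`.
#' @export
coactivation_index <- function(env_a, env_b, pair = c("A", "B"),
                               method = c("min_max", "rudolph")) {
  method <- match.arg(method)
  if (length(env_a) != length(env_b)) stop_param("envelopes must have equal length")
  if (any(env_a < 0) || any(env_b < 0)) stop_param("envelopes must be nonnegative")
  s_max <- sum(pmax(env_a, env_b))
  if (s_max == 0) stop_data("both envelopes are all-zero; coefficient undefined")
  coef <- if (method == "min_max") {
    sum(pmin(env_a, env_b)) / s_max
  } else {
    lo <- pmin(env_a, env_b)
    hi <- pmax(env_a, env_b)
    ratio <- ifelse(hi > 0, lo / hi, 0)
    sum(ratio * (lo + hi)) / sum(lo + hi)
  }
  structure(
    tibble(pair_a = pair[1], pair_b = pair[2], coefficient = coef,
           n_samples = length(env_a), normalization = method),
    class = c("coactivation_result", class(tibble())))
}

#' Coordination profile (L-shaped activation scatter)
#'
#' The paired activation scatter `(a_i, b_i)` of two normalized antagonist
#' envelopes, downsampled for plotting, plus an L-shape score: the fraction of
#' samples in which at least one muscle is nearly silent
#' (`min(a_i, b_i) < threshold`). Reciprocal activity hugs the axes (score
#' near 1, "L-shaped"); coactivation fills the diagonal (score near 0).
#'
#' @inheritParams coactivation_index
#' @param n_bins number of scatter points retained (evenly spaced in time,
#'   default 200).
#' @param threshold near-silence threshold on the normalized scale
#'   (default 0.1).
#' @return Object of class `coordination_profile`: list with `points`
#'   (tibble `a`, `b`), `l_shape_score`, `threshold`, `n_samples`, `pair`.
#' @export
coordination_profile <- function(env_a, env_b, n_bins = 200, pair = c("A", "B"),
                                 threshold = 0.1) {
  if (length(env_a) != length(env_b)) stop_param("envelopes must have equal length")
  n <- length(env_a)
  idx <- if (n > n_bins) unique(round(seq(1, n, length.out = n_bins))) else seq_len(n)
  score <- mean(pmin(env_a, env_b) < threshold)
  structure(
    list(points = tibble(a = env_a[idx], b = env_b[idx]),
         l_shape_score = score, threshold = threshold,
         n_samples = n, pair = pair),
    class = "coordination_profile")
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf("<coordination_profile> %s vs %s: L-shape score %.3f (%d samples)\n",
              x$pair[1], x$pair[2], x$l_shape_score, x$n_samples))
  invisible(x)
}

#' Default antagonist muscle pairs
#'
#' The antagonist pairings used for coordination profiling: biceps/triceps
#' brachii, carpal extensor/flexor, tibialis anterior/gastrocnemius, and
#' biceps/rectus femoris, right side by default.
#'
#' @param side `"R"` or `"L"` suffix for the channel labels.
#' @return Tibble with columns `a`, `b`, `group`.
#' @export
antagonist_pairs <- function(side = "R") {
  tibble(
    a = paste0(c("BIC", "EXT", "TA", "BF"), "_", side),
    b = paste0(c("TRIC", "FLE", "GM", "RF"), "_", side),
    group = c("forelimb_proximal", "forelimb_distal",
              "hindlimb_distal", "hindlimb_proximal"))
}

#' Coactivation table for a locomotor EMG recording
#'
#' Full chain from raw EMG to coactivation coefficients for a table of
#' antagonist pairs: band-pass + notch conditioning, rectification, linear
#' envelope, normalization, then [coactivation_index()] and the L-shape score
#' per pair.
#'
#' @param rec a [recording()] with the paired EMG channels.
#' @param pairs tibble with columns `a` and `b` of channel labels
#'   (default [antagonist_pairs()]).
#' @param cutoff envelope low-pass cutoff in Hz (default 10). Locomotor
#'   bursts last ~0.2-0.3 s; a cutoff much below ~1/burst-duration smears the
#'   burst edges into the antagonist's window and inflates the coefficient,
#'   so coactivation analysis uses a wider envelope bandwidth than the 5 Hz
#'   general-purpose default of [envelope()].
#' @param baseline_quantile resting-level estimate passed to
#'   [normalize_envelope()]; the lower quartile (0.25) sits inside the quiet
#'   phase for muscles active less than ~75 % of the cycle and removes the
#'   rectified-noise floor that would otherwise enter every coactivation
#'   numerator sample.
#' @param spec a [filter_spec()] for conditioning.
#' @param method coefficient definition, see [coactivation_index()].
#' @return Tibble with one row per pair: `pair_a`, `pair_b`, `group` (if
#'   provided), `coefficient`, `l_shape_score`, `n_samples`, `normalization`.
#' @export
coactivation_table <- function(rec, pairs = antagonist_pairs(), cutoff = 10,
                               baseline_quantile = 0.25,
                               spec = filter_spec(), method = "min_max") {
  missing <- setdiff(unique(c(pairs$a, pairs$b)), rec$channels$label)
  if (length(missing))
    stop_data(paste("channels listed in the pairing table are missing:",
                    paste(missing, collapse = ", ")))
  fs <- rec$sampling_rate
  env_of <- function(ch) {
    v <- channel_values(rec, ch)
    v <- bandpass_filter(v, spec, fs = fs)
    v <- notch_filter(v, spec, fs = fs)
    normalize_envelope(envelope(abs(v), cutoff = cutoff, fs = fs),
                       baseline_quantile = baseline_quantile)
  }
  envs <- lapply(unique(c(pairs$a, pairs$b)), env_of)
  names(envs) <- unique(c(pairs$a, pairs$b))
  purrr::pmap_dfr(pairs, function(a, b, ...) {
    res <- coactivation_index(envs[[a]], envs[[b]], pair = c(a, b), method = method)
    prof <- coordination_profile(envs[[a]], envs[[b]], pair = c(a, b))
    extra <- list(...)
    out <- tibble(pair_a = a, pair_b = b,
                  coefficient = res$coefficient,
                  l_shape_score = prof$l_shape_score,
                  n_samples = res$n_samples,
                  normalization = res$normalization)
    if (!is.null(extra$group)) out <- dplyr::mutate(out, group = extra$group,
                                                    .after = "pair_b")
    out
  })
}
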