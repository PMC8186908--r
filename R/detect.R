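#' Evoked-response detection configuration
#'
#' An ON call requires (i) a peak z-score above `z_threshold` and (ii) a
#' resolved rising and falling phase around an interior peak. The shape
#' criteria are deliberately noise-robust: they are evaluated on a lightly
#' smoothed copy of the trace (moving average of `shape_smooth_samples`),
#' whose in-window maximum must be interior and preceded by
#' `min_rise_samples` smoothed samples strictly below it (rising phase,
#' rejecting monotone drift and edge artifacts), while the
#' `min_fall_samples` raw samples after it must stay above baseline plus
#' `support_fraction` of the smoothed peak height (falling phase: a decay
#' resolved above the noise floor, rejecting single-sample spikes).
#' Strict per-sample monotonicity is not required, because adjacent to a
#' sampled smooth maximum the expected increment is near zero and a
#' monotone-run test fails at any signal-to-noise ratio. The peak amplitude,
#' z-score and latency are always measured on the raw trace.
#'
#' @param z_threshold Peak z threshold (default 3).
#' @param response_window_s Post-onset search window, seconds (1.0 for the
#'   in vivo design; 3.0 is typical for slow slice FA transients).
#' @param min_rise_samples,min_fall_samples Number of flanking samples
#'   checked on each side of the peak (>= 1; default 2).
#' @param baseline_len_s Pre-stimulus baseline length, seconds (default 2).
#' @param support_fraction Fraction of the smoothed peak height (above
#'   baseline) that the falling-phase samples must retain (default 0.25:
#'   deep enough that threshold-level noise peaks rarely carry it, shallow
#'   enough that a tau ~ 0.6 s calcium decay clears it two samples past the
#'   peak at 10 Hz).
#' @param shape_smooth_samples Width (samples) of the moving average used
#'   for the shape criteria (odd; default 3; 1 disables smoothing).
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(z_threshold = 3, response_window_s = 1,
                             min_rise_samples = 2, min_fall_samples = 2,
                             baseline_len_s = 2, support_fraction = 0.25,
                             shape_smooth_samples = 3) {
  if (z_threshold <= 0) stop("z_threshold must be positive")
  if (response_window_s <= 0) stop("response_window_s must be positive")
  if (min_rise_samples < 1 || min_fall_samples < 1)
    stop("min rise/fall sample counts must be >= 1")
  if (support_fraction < 0 || support_fraction >= 1)
    stop("support_fraction must lie in [0, 1)")
  if (shape_smooth_samples < 1 || shape_smooth_samples %% 2 == 0)
    stop("shape_smooth_samples must be odd and >= 1")
  structure(list(z_threshold = z_threshold,
                 response_window_s = response_window_s,
                 min_rise_samples = as.integer(min_rise_samples),
                 min_fall_samples = as.integer(min_fall_samples),
                 baseline_len_s = baseline_len_s,
                 support_fraction = support_fraction,
                 shape_smooth_samples = as.integer(shape_smooth_samples)),
            class = "detection_config")
}

#' Detect an evoked response in a delta-f/f trace
#'
#' The peak is the maximum of the trace within the half-open response window
#' `[onset, onset + response_window_s)` (ties broken by the earliest sample);
#' its z-score is `(peak - baseline mean) / baseline SD` on the delta-f/f
#' scale. The call is ON iff the z-score exceeds the threshold and the peak
#' shows a rising and a falling phase (see [detection_config()]). Rejections
#' are labelled `low_z`, `no_rise` or `no_fall`, in that order of precedence.
#'
#' @param trace A [dff_trace()] covering the response window, with a
#'   positive baseline SD.
#' @param cfg A [detection_config()].
#' @return A one-row `data.frame`: `is_on`, `peak_dff` (%), `peak_latency_s`
#'   (from onset), `zscore`, `reject_reason`.
#' @export
detect_evoked <- function(trace, cfg = detection_config()) {
  stopifnot(inherits(trace, "dff_trace"))
  if (!is.finite(trace$baseline_sd) || trace$baseline_sd <= 0)
    stop("baseline SD must be positive for z-scoring")
  onset <- trace$stim_onset_s
  win <- which(trace$times_s >= onset &
               trace$times_s < onset + cfg$response_window_s)
  if (!length(win) || max(trace$times_s) < onset + cfg$response_window_s -
        1 / trace$sampling_rate_hz - 1e-9)
    stop("response window exceeds the trace")
  y <- trace$values
  p <- win[which.max(y[win])]          # earliest index at ties
  peak <- y[p]
  z <- (peak - trace$baseline_mean) / trace$baseline_sd
  s <- if (cfg$shape_smooth_samples > 1L)
    smooth_reflect(y, rep(1, cfg$shape_smooth_samples) /
                     cfg$shape_smooth_samples)
  else y
  ps <- win[which.max(s[win])]         # shape assessed at the smoothed peak
  s_peak <- s[ps]
  s_height <- s_peak - trace$baseline_mean
  reason <- "none"
  if (z <= cfg$z_threshold) {
    reason <- "low_z"
  } else if (ps == win[1L] || ps - cfg$min_rise_samples < 1L ||
             any(s[(ps - cfg$min_rise_samples):(ps - 1L)] >= s_peak)) {
    reason <- "no_rise"
  } else if (ps == win[length(win)] ||
             ps + cfg$min_fall_samples > length(y) ||
             any(y[(ps + 1L):(ps + cfg$min_fall_samples)] <=
                   trace$baseline_mean + cfg$support_fraction * s_height)) {
    reason <- "no_fall"
  }
  data.frame(is_on = reason == "none",
             peak_dff = peak,
             peak_latency_s = trace$times_s[p] - onset,
             zscore = z,
             reject_reason = reason,
             stringsAsFactors = FALSE)
}

#' Classify every trial of an experiment as population ON or OFF
#'
#' Applies [detect_evoked()] to one delta-f/f trace per trial and returns a
#' per-trial classification table joined with the protocol metadata.
#'
#' @param traces List of [dff_trace()] (one per trial), or a [trace_set()]
#'   of raw counts (rows aligned with `protocols`, converted per trial with
#'   [dff_trace()]).
#' @param protocols A [trial_protocol()] table, one row per trace.
#' @param cfg A [detection_config()].
#' @return A `data.frame` of class `trial_classification` with columns
#'   `trial_id`, `level`, `is_on`, `peak_dff`, `peak_latency_s`, `zscore`,
#'   `reject_reason`, plus a `percent_on` attribute
#'   (`100 * n_ON / n_trials`).
#' @export
classify_trials <- function(traces, protocols, cfg = detection_config()) {
  if (inherits(traces, "trace_set")) {
    ts <- traces
    traces <- lapply(seq_len(nrow(ts$traces)), function(i)
      dff_trace(as.numeric(ts$traces[i, ]), ts$sampling_rate_hz,
                stim_onset_s = protocols$stim_onset_s[i],
                baseline_len_s = cfg$baseline_len_s, t0_s = ts$t0_s))
  }
  if (!length(traces)) stop("empty trial set")
  if (length(traces) != nrow(protocols))
    stop("one trace per protocol row is required")
  calls <- do.call(rbind, lapply(traces, detect_evoked, cfg = cfg))
  out <- cbind(data.frame(trial_id = protocols$trial_id,
                          level = protocols$level), calls)
  attr(out, "percent_on") <- 100 * mean(out$is_on)
  class(out) <- c("trial_classification", "data.frame")
  out
}

#' Percent population-ON responses of a classification table
#' @param calls A [classify_trials()] table.
#' @return Percent of trials classified ON (0-100).
#' @export
percent_on <- function(calls) 100 * mean(calls$is_on)

#' Histogram of peak delta-f/f amplitudes
#'
#' Bin edges are aligned to integer multiples of `bin_width` (1% bins by
#' default) and bins are half-open `[lo, hi)`; counts sum to the number of
#' values.
#'
#' @param peaks Numeric peak delta-f/f values (%).
#' @param bin_width Bin width in % (default 1).
#' @return A `data.frame` with `bin_lo`, `bin_hi`, `count`.
#' @export
amplitude_histogram <- function(peaks, bin_width = 1) {
  if (!length(peaks)) stop("need at least one value")
  if (bin_width <= 0) stop("bin width must be positive")
  lo <- floor(min(peaks) / bin_width)
  hi <- floor(max(peaks) / bin_width)
  edges <- (lo:(hi + 1L)) * bin_width
  idx <- floor(peaks / bin_width) - lo + 1L
  counts <- tabulate(idx, nbins = hi - lo + 1L)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
             count = counts)
}

#' Percent-ON as a function of stimulus level
#'
#' Summarizes a classification table by stimulus level and, when requested,
#' fits the logistic gating curve `p(level) = 1 / (1 + exp(-(level - s50) /
#' k))` by binomial maximum likelihood, returning the midpoint `s50` and
#' slope parameter `k`.
#'
#' @param calls A [classify_trials()] table with a `level` column
#'   (>= 2 distinct levels, each with >= 1 trial).
#' @param fit Fit the logistic curve (default TRUE).
#' @return A `data.frame` (`level`, `n`, `n_on`, `percent_on`); when
#'   `fit = TRUE` it carries a `fit` attribute with `s50` and `k`.
#' @export
percent_on_by_level <- function(calls, fit = TRUE) {
  lv <- sort(unique(calls$level))
  if (length(lv) < 2L) stop("need at least two stimulus levels")
  agg <- do.call(rbind, lapply(lv, function(l) {
    sub <- calls[calls$level == l, ]
    data.frame(level = l, n = nrow(sub), n_on = sum(sub$is_on),
               percent_on = 100 * mean(sub$is_on))
  }))
  if (any(agg$n == 0L)) stop("level with zero trials")
  if (fit) {
    gfit <- stats::glm(cbind(n_on, n - n_on) ~ level, family = stats::binomial,
                       data = agg)
    beta <- stats::coef(gfit)
    attr(agg, "fit") <- list(s50 = unname(-beta[1L] / beta[2L]),
                             k = unname(1 / beta[2L]))
  }
  agg
}
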