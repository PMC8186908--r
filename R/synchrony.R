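#' Peak latency of an activated cell
#'
#' Latency of the delta-f/f maximum within the post-stimulus search window,
#' relative to stimulus onset. Only activated cells carry a latency: the
#' trace must first pass [detect_evoked()]; non-activated cells are excluded
#' (an error), never zero-filled.
#'
#' @param trace A [dff_trace()] for one cell on one trial.
#' @param cfg A [detection_config()]; `response_window_s` is the search
#'   window.
#' @return Peak latency in seconds from onset. Ties go to the earliest
#'   sample.
#' @export
cell_peak_latency <- function(trace, cfg = detection_config()) {
  call <- detect_evoked(trace, cfg)
  if (!call$is_on)
    stop(sprintf("cell not activated on this trial (%s); excluded",
                 call$reject_reason))
  call$peak_latency_s
}

#' Build a cell x trial latency table
#'
#' Runs [detect_evoked()] on every cell/trial trace and keeps the activated
#' ones, yielding the long-format table that the per-trial variance and CDF
#' summaries consume.
#'
#' @param cell_traces Nested list: `cell_traces[[cell]][[trial]]` is a
#'   [dff_trace()]. Names are used as ids when present.
#' @param cfg A [detection_config()].
#' @return A `data.frame` with `cell_id`, `trial_id`, `peak_latency_s`
#'   (activated cells only).
#' @export
latency_table <- function(cell_traces, cfg = detection_config()) {
  cells <- names(cell_traces)
  if (is.null(cells)) cells <- as.character(seq_along(cell_traces))
  rows <- list()
  for (ci in seq_along(cell_traces)) {
    trials <- names(cell_traces[[ci]])
    if (is.null(trials)) trials <- as.character(seq_along(cell_traces[[ci]]))
    for (ti in seq_along(cell_traces[[ci]])) {
      call <- detect_evoked(cell_traces[[ci]][[ti]], cfg)
      if (call$is_on)
        rows[[length(rows) + 1L]] <-
          data.frame(cell_id = cells[ci], trial_id = trials[ti],
                     peak_latency_s = call$peak_latency_s,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(cell_id = character(), trial_id = character(),
                      peak_latency_s = numeric()))
  do.call(rbind, rows)
}

#' Across-cell peak-latency variance of one trial
#'
#' Unbiased sample variance (n - 1 denominator) of the peak latencies of the
#' cells activated on a single trial; the population synchrony metric
#' (larger variance = less synchronous).
#'
#' @param latencies Numeric latencies (seconds) of >= 2 activated cells.
#' @return Sample variance in s^2.
#' @export
trial_latency_variance <- function(latencies) {
  latencies <- latencies[is.finite(latencies)]
  if (length(latencies) < 2L)
    stop("latency variance needs >= 2 activated cells")
  stats::var(latencies)
}

#' Per-trial latency variances of a latency table
#'
#' @param lat A [latency_table()]-style data frame.
#' @return `data.frame` with `trial_id`, `n_cells`, `latency_var_s2`
#'   (trials with >= 2 activated cells only).
#' @export
latency_variance_by_trial <- function(lat) {
  ids <- unique(lat$trial_id)
  rows <- lapply(ids, function(tid) {
    l <- lat$peak_latency_s[lat$trial_id == tid]
    if (length(l) < 2L) return(NULL)
    data.frame(trial_id = tid, n_cells = length(l),
               latency_var_s2 = trial_latency_variance(l),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no trial has >= 2 activated cells")
  out
}

#' Pair population-ON and population-OFF latency variances
#'
#' Builds the paired (var_ON, var_OFF) samples that feed the paired test of
#' the synchrony comparison. Two pairing rules are available:
#' `"nearest"` (default) pairs each OFF trial with the nearest-in-time ON
#' trial of the same field of view, using each ON trial at most once;
#' `"mean"` forms one pair per field of view from the means of the ON and
#' OFF per-trial variances.
#'
#' @param trial_vars Output of [latency_variance_by_trial()], optionally
#'   with a `fov` column (single field assumed otherwise).
#' @param classification A [classify_trials()] table (or any data frame with
#'   `trial_id` and `is_on`) labelling the trials.
#' @param trial_times Optional named vector of trial onset times used by the
#'   nearest rule; defaults to trial order.
#' @param rule `"nearest"` or `"mean"`.
#' @return `data.frame` with `fov`, `var_on`, `var_off`, one row per pair.
#' @export
paired_on_off_variances <- function(trial_vars, classification,
                                    trial_times = NULL,
                                    rule = c("nearest", "mean")) {
  rule <- match.arg(rule)
  tv <- merge(trial_vars,
              classification[, c("trial_id", "is_on")], by = "trial_id")
  if (is.null(tv$fov)) tv$fov <- "fov1"
  if (is.null(trial_times)) {
    trial_times <- stats::setNames(seq_along(unique(tv$trial_id)),
                                   unique(tv$trial_id))
  }
  tv$t <- as.numeric(trial_times[as.character(tv$trial_id)])
  pairs <- list()
  for (f in unique(tv$fov)) {
    on <- tv[tv$fov == f & tv$is_on, ]
    off <- tv[tv$fov == f & !tv$is_on, ]
    if (!nrow(on) || !nrow(off)) next
    if (rule == "mean") {
      pairs[[f]] <- data.frame(fov = f, var_on = mean(on$latency_var_s2),
                               var_off = mean(off$latency_var_s2))
    } else {
      avail <- rep(TRUE, nrow(on))
      for (i in order(off$t)) {
        if (!any(avail)) break
        j <- which(avail)[which.min(abs(on$t[avail] - off$t[i]))]
        pairs[[length(pairs) + 1L]] <-
          data.frame(fov = f, var_on = on$latency_var_s2[j],
                     var_off = off$latency_var_s2[i])
        avail[j] <- FALSE
      }
    }
  }
  if (!length(pairs)) stop("no valid ON/OFF pairs")
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Empirical CDF of peak latencies
#'
#' Right-continuous empirical distribution function, evaluated at the sorted
#' unique latencies; `F(max) = 1`.
#'
#' @param latencies Numeric latencies of one group (>= 1 value).
#' @return `data.frame` with `latency_s` and `cdf`.
#' @export
latency_cdf <- function(latencies) {
  latencies <- latencies[is.finite(latencies)]
  if (!length(latencies)) stop("empty latency group")
  xs <- sort(unique(latencies))
  data.frame(latency_s = xs, cdf = stats::ecdf(latencies)(xs))
}
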