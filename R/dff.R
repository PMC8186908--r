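#' Neuropil correction configuration
#'
#' Perisomatic background is estimated inside an ellipse whose radii are
#' `ellipse_scale` times those of the cell ROI, minus every cell ROI in the
#' field (to eliminate overlap); `subtraction_fraction` of that background
#' mean is subtracted from the cell mean before the delta-f/f step.
#'
#' @param ellipse_scale Radial scale of the background ellipse (> 1;
#'   default 2.25).
#' @param subtraction_fraction Fraction of the background subtracted
#'   (in `[0, 1]`; default 0.40).
#' @return A list of class `neuropil_config`.
#' @export
neuropil_config <- function(ellipse_scale = 2.25, subtraction_fraction = 0.40) {
  if (ellipse_scale <= 1) stop("ellipse_scale must exceed 1")
  if (subtraction_fraction < 0 || subtraction_fraction > 1)
    stop("subtraction_fraction must lie in [0, 1]")
  structure(list(ellipse_scale = ellipse_scale,
                 subtraction_fraction = subtraction_fraction),
            class = "neuropil_config")
}

#' Mean ROI fluorescence over time
#'
#' Unweighted per-frame mean of the raw counts of all pixels in the ROI.
#'
#' @param stack An [imaging_stack()].
#' @param roi An [roi()] lying within the frame bounds.
#' @return Numeric vector of length T (counts).
#' @export
roi_mean_trace <- function(stack, roi) {
  stopifnot(inherits(stack, "imaging_stack"), inherits(roi, "roi"))
  d <- dim(stack$frames)
  mask <- roi_mask(roi, d[2:3])
  if (!any(mask)) stop(sprintf("ROI '%s' is empty", roi$id))
  ell <- roi_ellipse(roi)
  if (is.null(roi$mask) &&
      (any(ell$center - ell$radii < -0.5) ||
       ell$center[1L] + ell$radii[1L] > d[2L] - 0.5 ||
       ell$center[2L] + ell$radii[2L] > d[3L] - 0.5))
    stop(sprintf("ROI '%s' extends beyond the frame", roi$id))
  flat <- matrix(stack$frames, nrow = d[1L])  # T x (H*W), column-major HxW
  rowMeans(flat[, as.vector(mask), drop = FALSE])
}

#' Delta-f/f trace from a raw fluorescence trace
#'
#' `values[t] = 100 * (raw[t] - f0) / f0` with `f0` the mean of the raw
#' trace over the `baseline_len_s` seconds preceding the stimulus onset
#' (half-open window `[onset - baseline_len_s, onset)`). The baseline mean
#' and SD of the delta-f/f values over the same window are recorded for
#' later z-scoring.
#'
#' @param raw Numeric raw-counts trace, or a single-row [trace_set()].
#' @param sampling_rate_hz Sampling rate of `raw` (ignored for trace sets).
#' @param stim_onset_s Stimulus onset, seconds on the same clock as `t0_s`.
#' @param baseline_len_s Baseline length in seconds (default 2).
#' @param t0_s Time of the first sample (default 0).
#' @param source_roi Optional ROI id recorded in the result.
#' @return An object of class `dff_trace`: percent delta-f/f `values`, the
#'   sample times, `f0`, and baseline statistics on the percent scale.
#' @export
dff_trace <- function(raw, sampling_rate_hz, stim_onset_s,
                      baseline_len_s = 2, t0_s = 0, source_roi = NA_character_) {
  if (inherits(raw, "trace_set")) {
    if (nrow(raw$traces) != 1L)
      stop("pass a single-row trace_set or a numeric vector")
    sampling_rate_hz <- raw$sampling_rate_hz
    t0_s <- raw$t0_s
    raw <- as.numeric(raw$traces[1L, ])
  }
  times <- t0_s + (seq_along(raw) - 1L) / sampling_rate_hz
  base_idx <- which(times >= stim_onset_s - baseline_len_s &
                    times < stim_onset_s)
  if (length(base_idx) < 2L)
    stop("insufficient pre-stimulus samples for the baseline window")
  f0 <- mean(raw[base_idx])
  if (f0 <= 0) stop("baseline mean f0 must be positive")
  values <- 100 * (raw - f0) / f0
  structure(list(values = values, times_s = times,
                 sampling_rate_hz = sampling_rate_hz,
                 stim_onset_s = stim_onset_s,
                 baseline_window_s = c(stim_onset_s - baseline_len_s,
                                       stim_onset_s),
                 f0 = f0,
                 baseline_mean = mean(values[base_idx]),
                 baseline_sd = stats::sd(values[base_idx]),
                 source_roi = source_roi),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf(
    "<dff_trace> %d samples @ %g Hz, f0 = %.4g, baseline sd = %.3g %%dff\n",
    length(x$values), x$sampling_rate_hz, x$f0, x$baseline_sd))
  invisible(x)
}

window_dff <- function(frames_flat, idx_base, idx_win) {
  # per-pixel dff (fraction) of the mean over a response window
  f0 <- colMeans(frames_flat[idx_base, , drop = FALSE])
  fw <- colMeans(frames_flat[idx_win, , drop = FALSE])
  if (any(f0 <= 0)) stop("non-positive per-pixel baseline")
  (fw - f0) / f0
}

#' Two-condition delta-f/f response map
#'
#' The in vivo trial design interleaves a silent condition (C0) and a
#' stimulus condition (C1), 10 s each; the response window is the 1 s
#' starting at the 5th second of C0 and at sound onset (also the 5th second)
#' of C1. Per pixel, each condition's delta-f/f is the mean over its response
#' window relative to that condition's own pre-window baseline (the 5
#' stimulus-free seconds preceding the window), and the map is the C1 - C0
#' difference so that sound-evoked activation is positive.
#'
#' @param stack_c0,stack_c1 [imaging_stack()]s covering one condition each,
#'   equal geometry and frame rate.
#' @param protocol A single-trial [trial_protocol()] row giving
#'   `response_window_s` (default 1 s) and `condition_dur_s`.
#' @return An object of class `dff_map`: H x W percent delta-f/f values plus
#'   window metadata.
#' @export
two_condition_dff_map <- function(stack_c0, stack_c1, protocol) {
  stopifnot(inherits(stack_c0, "imaging_stack"),
            inherits(stack_c1, "imaging_stack"))
  if (!identical(dim(stack_c0$frames), dim(stack_c1$frames)))
    stop("condition stacks must have equal geometry")
  if (stack_c0$frame_rate_hz != stack_c1$frame_rate_hz)
    stop("condition stacks must share a frame rate")
  win_len <- protocol$response_window_s[1L]
  win_start <- 5
  if (win_start + win_len > protocol$condition_dur_s[1L])
    stop("response window extends beyond the condition")
  one_condition <- function(stack) {
    d <- dim(stack$frames)
    times <- stack_times(stack) - stack$t0_s  # within-condition clock
    idx_base <- which(times >= 0 & times < win_start)
    idx_win <- which(times >= win_start & times < win_start + win_len)
    if (!length(idx_win)) stop("response window outside stack")
    window_dff(matrix(stack$frames, nrow = d[1L]), idx_base, idx_win)
  }
  d <- dim(stack_c0$frames)
  vals <- 100 * (one_condition(stack_c1) - one_condition(stack_c0))
  structure(list(values = matrix(vals, d[2L], d[3L]),
                 response_window_s = c(win_start, win_start + win_len)),
            class = "dff_map")
}

#' @export
print.dff_map <- function(x, ...) {
  cat(sprintf("<dff_map> %d x %d px, window [%g, %g) s, range [%.3g, %.3g] %%\n",
              nrow(x$values), ncol(x$values), x$response_window_s[1L],
              x$response_window_s[2L], min(x$values), max(x$values)))
  invisible(x)
}

#' Neuropil-corrected cell trace
#'
#' Perisomatic background contamination is removed from a cell's raw trace
#' before delta-f/f: the background region is the cell's equivalent ellipse
#' scaled by `cfg$ellipse_scale`, minus the union of all cell ROIs in the
#' field, and `corrected[t] = cell_mean[t] -
#' cfg$subtraction_fraction * background_mean[t]`.
#'
#' @param stack An [imaging_stack()].
#' @param cell The cell [roi()] to correct.
#' @param all_cells List of every cell [roi()] in the field (including
#'   `cell`); these are excluded from the background region.
#' @param cfg A [neuropil_config()].
#' @return Numeric corrected raw trace (counts), length T, suitable as
#'   input to [dff_trace()].
#' @export
neuropil_corrected_trace <- function(stack, cell, all_cells = list(cell),
                                     cfg = neuropil_config()) {
  stopifnot(inherits(stack, "imaging_stack"), inherits(cell, "roi"))
  d <- dim(stack$frames)
  hw <- d[2:3]
  cell_mask <- roi_mask(cell, hw)
  annulus <- roi_mask(cell, hw, scale = cfg$ellipse_scale)
  for (other in all_cells) annulus <- annulus & !roi_mask(other, hw)
  if (!any(annulus))
    stop("background region empty after excluding cell ROIs")
  flat <- matrix(stack$frames, nrow = d[1L])
  cell_mean <- rowMeans(flat[, as.vector(cell_mask), drop = FALSE])
  bg_mean <- rowMeans(flat[, as.vector(annulus), drop = FALSE])
  cell_mean - cfg$subtraction_fraction * bg_mean
}
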