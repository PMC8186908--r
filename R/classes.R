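#' Imaging stack
#'
#' Container for a multi-frame fluorescence recording: a T x H x W array of
#' raw counts together with its acquisition metadata. Flavoprotein
#' autofluorescence (FA) stacks are acquired at 4 Hz, calcium stacks at 10 Hz.
#'
#' @param frames Numeric array with dimensions T x H x W (frames, rows,
#'   columns). All values must be finite and non-negative; T >= 2.
#' @param frame_rate_hz Frames per second (> 0).
#' @param channel Signal kind, `"FA"` or `"calcium"`.
#' @param t0_s Time of the first frame relative to trial start, in seconds.
#'
#' @return An object of class `imaging_stack`.
#' @export
imaging_stack <- function(frames, frame_rate_hz,
                          channel = c("FA", "calcium"), t0_s = 0) {
  channel <- match.arg(channel)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (T x H x W)")
  if (dim(frames)[1L] < 2L)
    stop("stack must contain at least 2 frames")
  if (!all(is.finite(frames)))
    stop("all frame values must be finite")
  if (any(frames < 0))
    stop("frame values must be non-negative counts")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      !is.finite(frame_rate_hz) || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be a single positive number")
  structure(
    list(frames = frames, frame_rate_hz = as.numeric(frame_rate_hz),
         channel = channel, t0_s = as.numeric(t0_s)),
    class = "imaging_stack")
}

#' @export
print.imaging_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<imaging_stack> %s, %d frames of %d x %d px @ %g Hz, t0 = %g s\n",
              x$channel, d[1L], d[2L], d[3L], x$frame_rate_hz, x$t0_s))
  invisible(x)
}

#' Frame times of an imaging stack
#'
#' @param stack An [imaging_stack()].
#' @return Numeric vector of frame times in seconds (start-of-frame,
#'   half-open convention).
#' @export
stack_times <- function(stack) {
  stopifnot(inherits(stack, "imaging_stack"))
  stack$t0_s + (seq_len(dim(stack$frames)[1L]) - 1L) / stack$frame_rate_hz
}

#' Region of interest
#'
#' An ROI is either a boolean mask over the frame, or an ellipse given by a
#' center and per-axis radii in pixel units. When both are supplied the mask
#' takes precedence for pixel averaging; the ellipse is retained as geometry
#' (e.g. for neuropil annuli). Coordinates are 0-based `(row, col)`.
#'
#' @param id Character identifier.
#' @param kind `"region"` (a brain area) or `"cell"` (a soma).
#' @param mask Optional logical H x W matrix; must contain at least one TRUE.
#' @param center Optional numeric length-2 `(row, col)` ellipse center, px.
#' @param radii Optional numeric length-2 `(row, col)` ellipse radii, px (> 0).
#'
#' @return An object of class `roi`.
#' @export
roi <- function(id, kind = c("region", "cell"), mask = NULL,
                center = NULL, radii = NULL) {
  kind <- match.arg(kind)
  if (is.null(mask) && (is.null(center) || is.null(radii)))
    stop("an ROI needs a mask or an ellipse (center + radii)")
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !is.logical(mask))
      stop("`mask` must be a logical matrix")
    if (!any(mask)) stop("ROI mask is empty")
  }
  if (!is.null(radii)) {
    if (length(radii) != 2L || any(!is.finite(radii)) || any(radii <= 0))
      stop("ellipse radii must be two positive numbers")
    if (length(center) != 2L || any(!is.finite(center)))
      stop("ellipse center must be two finite numbers")
  }
  structure(list(id = as.character(id), kind = kind, mask = mask,
                 center = if (!is.null(center)) as.numeric(center),
                 radii = if (!is.null(radii)) as.numeric(radii)),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  geom <- if (!is.null(x$mask)) sprintf("mask (%d px)", sum(x$mask))
          else sprintf("ellipse c=(%g,%g) r=(%g,%g)",
                       x$center[1L], x$center[2L], x$radii[1L], x$radii[2L])
  cat(sprintf("<roi> '%s' [%s] %s\n", x$id, x$kind, geom))
  invisible(x)
}

#' Rasterize an ROI to a logical mask
#'
#' Ellipses use the inclusive test
#' `((row - c_r)/r_r)^2 + ((col - c_c)/r_c)^2 <= 1` over 0-based pixel
#' centers. A stored mask is returned as-is (cropped/validated against the
#' frame geometry).
#'
#' @param x An [roi()].
#' @param dim_hw Integer length-2 frame size `(H, W)`.
#' @param scale Radial scale factor applied to ellipse radii (used for
#'   neuropil annuli); ignored for mask ROIs.
#' @return Logical H x W matrix.
#' @export
roi_mask <- function(x, dim_hw, scale = 1) {
  stopifnot(inherits(x, "roi"), length(dim_hw) == 2L)
  if (!is.null(x$mask) && scale == 1) {
    if (!identical(dim(x$mask), as.integer(dim_hw)))
      stop(sprintf("ROI '%s' mask is %d x %d but frame is %d x %d", x$id,
                   nrow(x$mask), ncol(x$mask), dim_hw[1L], dim_hw[2L]))
    return(x$mask)
  }
  ell <- roi_ellipse(x)
  rr <- matrix(0:(dim_hw[1L] - 1L), dim_hw[1L], dim_hw[2L])
  cc <- matrix(0:(dim_hw[2L] - 1L), dim_hw[1L], dim_hw[2L], byrow = TRUE)
  ((rr - ell$center[1L]) / (ell$radii[1L] * scale))^2 +
    ((cc - ell$center[2L]) / (ell$radii[2L] * scale))^2 <= 1
}

#' Equivalent ellipse of an ROI
#'
#' For ellipse ROIs returns the stored geometry. For mask-only ROIs returns
#' the mask centroid with per-axis radii equal to twice the RMS deviation of
#' member pixels (the radius a uniform-density ellipse of the same second
#' moment would have).
#'
#' @param x An [roi()].
#' @return List with `center` and `radii` (0-based px).
#' @export
roi_ellipse <- function(x) {
  stopifnot(inherits(x, "roi"))
  if (!is.null(x$center) && !is.null(x$radii))
    return(list(center = x$center, radii = x$radii))
  idx <- which(x$mask, arr.ind = TRUE) - 1  # 0-based
  ctr <- colMeans(idx)
  dev <- sweep(idx, 2L, ctr)
  rms <- sqrt(colMeans(dev^2))
  rad <- pmax(2 * rms, 0.5)  # a single-pixel mask still has a finite ellipse
  list(center = as.numeric(ctr), radii = as.numeric(rad))
}

#' Trial protocol table
#'
#' One row per trial: stimulus onset, kind, level and optional two-condition
#' metadata. Levels are dB SPL for tones and microamperes for electrical
#' stimulation. Condition `C0` rows carry no stimulus (the silent reference
#' condition of the in vivo two-condition design).
#'
#' @param trial_id Integer trial identifiers (unique).
#' @param stim_onset_s Stimulus onsets in seconds from recording start (>= 0).
#' @param stim_kind `"tone"` or `"electrical"` (recycled).
#' @param level Stimulus level, dB SPL or uA (>= 0; recycled).
#' @param condition Optional `"C0"`/`"C1"` factor for the in vivo design.
#' @param condition_dur_s Condition length in seconds (default 10).
#' @param response_window_s Response-window length in seconds (default 1).
#'
#' @return A `data.frame` of class `trial_protocol`.
#' @export
trial_protocol <- function(trial_id, stim_onset_s, stim_kind = "tone",
                           level = 0, condition = NA_character_,
                           condition_dur_s = 10, response_window_s = 1) {
  trial_id <- as.integer(trial_id)
  if (anyDuplicated(trial_id)) stop("trial ids must be unique")
  if (any(stim_onset_s < 0)) stop("stim_onset_s must be >= 0")
  if (any(level < 0)) stop("level must be >= 0")
  if (!all(stim_kind %in% c("tone", "electrical")))
    stop("stim_kind must be 'tone' or 'electrical'")
  if (!all(is.na(condition) | condition %in% c("C0", "C1")))
    stop("condition must be NA, 'C0' or 'C1'")
  lvl <- rep_len(as.numeric(level), length(trial_id))
  cond <- rep_len(as.character(condition), length(trial_id))
  if (any(!is.na(cond) & cond == "C0" & lvl > 0))
    stop("C0 trials carry no stimulus (level must be 0)")
  out <- data.frame(
    trial_id = trial_id,
    stim_onset_s = as.numeric(stim_onset_s),
    stim_kind = rep_len(stim_kind, length(trial_id)),
    level = lvl,
    condition = cond,
    condition_dur_s = rep_len(as.numeric(condition_dur_s), length(trial_id)),
    response_window_s = rep_len(as.numeric(response_window_s),
                                length(trial_id)))
  class(out) <- c("trial_protocol", "data.frame")
  out
}

#' Trace set
#'
#' A trials (or cells) x samples matrix of uniformly sampled traces with a
#' declared unit and alignment metadata. Rows are named by trial/cell id.
#'
#' @param traces Numeric matrix, one row per trace.
#' @param sampling_rate_hz Sampling rate (> 0).
#' @param unit Physical unit of the samples (e.g. `"counts"`, `"%dff"`,
#'   `"mV"`, `"pA"`). Must be declared.
#' @param t0_s Time of the first sample relative to stimulus onset (so the
#'   onset sits at `-t0_s` into each row); default 0.
#' @param ids Optional row identifiers.
#'
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces, sampling_rate_hz, unit, t0_s = 0, ids = NULL) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1L)
  if (!is.matrix(traces) || !is.numeric(traces))
    stop("`traces` must be a numeric matrix")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be positive")
  if (missing(unit) || is.null(unit) || !nzchar(unit))
    stop("unit missing: trace sets must declare their unit")
  if (!is.null(ids)) rownames(traces) <- as.character(ids)
  if (is.null(rownames(traces)))
    rownames(traces) <- as.character(seq_len(nrow(traces)))
  structure(list(traces = traces,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 unit = unit, t0_s = as.numeric(t0_s)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d traces x %d samples @ %g Hz [%s], t0 = %g s\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate_hz, x$unit,
              x$t0_s))
  invisible(x)
}

#' Sample times of a trace set
#' @param x A [trace_set()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(x) {
  stopifnot(inherits(x, "trace_set"))
  x$t0_s + (seq_len(ncol(x$traces)) - 1L) / x$sampling_rate_hz
}

#' Electrophysiology trace
#'
#' A single continuous recording with its modality. Voltage-clamp traces
#' (`"PSC"`) must declare the holding potential: +10 mV isolates IPSCs,
#' -60 mV isolates EPSCs.
#'
#' @param samples Numeric vector, mV (LFP/Vm) or pA (PSC).
#' @param sampling_rate_hz Sampling rate; acquisition nominal is 20 kHz.
#' @param modality `"LFP"`, `"Vm"` or `"PSC"`.
#' @param holding_mv Holding potential in mV; required iff modality = "PSC".
#' @param t0_s Time of the first sample relative to trial start.
#'
#' @return An object of class `ephys_trace`.
#' @export
ephys_trace <- function(samples, sampling_rate_hz = 20000,
                        modality = c("LFP", "Vm", "PSC"),
                        holding_mv = NULL, t0_s = 0) {
  modality <- match.arg(modality)
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (sampling_rate_hz <= 0) stop("sampling rate must be positive")
  if (modality == "PSC" && is.null(holding_mv))
    stop("PSC traces must declare holding_mv (+10 IPSC, -60 EPSC)")
  if (modality != "PSC" && !is.null(holding_mv))
    stop("holding_mv applies to PSC traces only")
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 modality = modality,
                 holding_mv = if (!is.null(holding_mv)) as.numeric(holding_mv),
                 t0_s = as.numeric(t0_s)),
            class = "ephys_trace")
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples @ %g Hz%s\n", x$modality,
              length(x$samples), x$sampling_rate_hz,
              if (!is.null(x$holding_mv))
                sprintf(", held at %+g mV", x$holding_mv) else ""))
  invisible(x)
}
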