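#' @importFrom mclust Mclust mclustBIC
NULL

gaussian_fir <- function(sigma_s, fs) {
  # symmetric FIR truncated at 4 sigma, normalized to unit DC gain
  half <- max(1L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma_s^2))
  k / sum(k)
}

smooth_reflect <- function(x, kernel) {
  # zero-phase FIR smoothing with reflected edges
  half <- (length(kernel) - 1L) %/% 2L
  xp <- c(rev(x[seq_len(half) + 1L]), x,
          rev(x[length(x) - seq_len(half)]))
  out <- stats::filter(xp, kernel, sides = 2L)
  as.numeric(out[(half + 1L):(half + length(x))])
}

#' Condition an LFP trace
#'
#' Zero-phase Gaussian low-pass (FIR, -3 dB at `lowpass_hz`) followed by a
#' zero-phase second-order IIR notch at `notch_hz` (applied
#' forward-backward). DC gain is 1.
#'
#' @param trace An [ephys_trace()] with modality `"LFP"`.
#' @param lowpass_hz -3 dB point of the Gaussian low-pass (default 300 Hz).
#' @param notch_hz Notch center frequency (default 60 Hz).
#' @param q Notch quality factor (default 30).
#' @return The filtered [ephys_trace()].
#' @export
filter_lfp <- function(trace, lowpass_hz = 300, notch_hz = 60, q = 30) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$modality != "LFP") stop("filter_lfp expects an LFP trace")
  fs <- trace$sampling_rate_hz
  if (fs <= 2 * notch_hz * 10)
    stop("sampling rate too low for the notch filter")
  # Gaussian with H(f) = exp(-2 pi^2 sigma^2 f^2); -3 dB at f0 gives
  # sigma = sqrt(log(2)) / (2 pi f0)
  sigma_s <- sqrt(log(2)) / (2 * pi * lowpass_hz)
  y <- smooth_reflect(trace$samples, gaussian_fir(sigma_s, fs))
  # biquad notch, unity DC gain, applied forward-backward (zero phase)
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  y <- signal::filtfilt(signal::Arma(b = b, a = a), y)
  out <- trace
  out$samples <- as.numeric(y)
  out
}

#' Population ON/OFF call from an LFP trace
#'
#' The post-stimulus LFP deflection is rectified about the pre-stimulus
#' baseline mean, envelope-smoothed (Gaussian, `envelope_sd_s`), decimated
#' to `envelope_rate_hz`, and passed to the same z > 3 detector used for the
#' imaging traces ([detect_evoked()]). A stimulus-artifact blanking window
#' after onset is replaced by the baseline mean before rectification. The
#' use of the imaging criteria on LFP is an extension of the imaging
#' two-criteria rule, flagged here by configuration rather than hard-coded.
#'
#' @param trace A (filtered) LFP [ephys_trace()].
#' @param onset_s Stimulus onset on the trace clock.
#' @param cfg A [detection_config()].
#' @param blank_s Artifact blanking window after onset (default 10 ms).
#' @param envelope_sd_s Envelope smoothing SD (default 25 ms).
#' @param envelope_rate_hz Envelope sampling rate fed to the detector
#'   (default 100 Hz).
#' @return A one-row classification `data.frame` as from [detect_evoked()].
#' @export
lfp_response_call <- function(trace, onset_s, cfg = detection_config(),
                              blank_s = 0.01, envelope_sd_s = 0.025,
                              envelope_rate_hz = 100) {
  stopifnot(inherits(trace, "ephys_trace"))
  fs <- trace$sampling_rate_hz
  times <- trace$t0_s + (seq_along(trace$samples) - 1L) / fs
  base_idx <- which(times >= onset_s - cfg$baseline_len_s & times < onset_s)
  if (length(base_idx) < 2L) stop("insufficient pre-stimulus baseline")
  x <- trace$samples
  mu <- mean(x[base_idx])
  x[times >= onset_s & times < onset_s + blank_s] <- mu
  env <- smooth_reflect(abs(x - mu), gaussian_fir(envelope_sd_s, fs))
  step <- max(1L, round(fs / envelope_rate_hz))
  keep <- seq(1L, length(env), by = step)
  env_ts <- trace_set(env[keep], sampling_rate_hz = fs / step, unit = "mV",
                      t0_s = times[1L])
  # reuse the two-criteria detector on the envelope; the envelope has a
  # positive baseline so the dff machinery is bypassed by z-scoring directly
  env_trace <- structure(list(
    values = as.numeric(env[keep]),
    times_s = trace_times(env_ts),
    sampling_rate_hz = fs / step,
    stim_onset_s = onset_s,
    baseline_window_s = c(onset_s - cfg$baseline_len_s, onset_s),
    f0 = NA_real_,
    baseline_mean = mean(env[keep][trace_times(env_ts) < onset_s &
      trace_times(env_ts) >= onset_s - cfg$baseline_len_s]),
    baseline_sd = stats::sd(env[keep][trace_times(env_ts) < onset_s &
      trace_times(env_ts) >= onset_s - cfg$baseline_len_s]),
    source_roi = NA_character_), class = "dff_trace")
  detect_evoked(env_trace, cfg)
}

#' Postsynaptic-current charge (AUC) and peak latency
#'
#' Charge transferred by the evoked current: the absolute trapezoidal
#' integral of the baseline-subtracted current over
#' `[onset + blank_s, onset + window_s]`, in pC (pA * s). The peak latency
#' is the time of the current extremum in the same span: the maximum for
#' IPSCs (outward at +10 mV), the minimum for EPSCs (inward at -60 mV).
#'
#' @param trace An [ephys_trace()] with modality `"PSC"`.
#' @param onset_s Stimulus onset on the trace clock.
#' @param window_s Integration window length after onset (default 1 s).
#' @param blank_s Stimulus-artifact blanking after onset (default 10 ms).
#' @param baseline_len_s Pre-stimulus baseline length (default 0.5 s,
#'   the minimum).
#' @return A one-row `data.frame`: `kind` (IPSC/EPSC from the holding
#'   potential), `auc_pc`, `peak_latency_s`, `peak_pa`.
#' @export
psc_charge <- function(trace, onset_s, window_s = 1, blank_s = 0.01,
                       baseline_len_s = 0.5) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$modality != "PSC") stop("psc_charge expects a PSC trace")
  if (baseline_len_s < 0.5) stop("pre-stimulus baseline must be >= 0.5 s")
  kind <- if (trace$holding_mv > -20) "IPSC" else "EPSC"
  fs <- trace$sampling_rate_hz
  times <- trace$t0_s + (seq_along(trace$samples) - 1L) / fs
  base_idx <- which(times >= onset_s - baseline_len_s & times < onset_s)
  if (length(base_idx) < 2L) stop("insufficient pre-stimulus baseline")
  win <- which(times >= onset_s + blank_s & times <= onset_s + window_s)
  if (!length(win) || max(times) < onset_s + window_s - 1 / fs)
    stop("integration window exceeds the trace")
  i0 <- mean(trace$samples[base_idx])
  dev <- trace$samples[win] - i0
  auc <- abs(pracma::trapz(times[win], dev))
  p <- if (kind == "IPSC") win[which.max(dev)] else win[which.min(dev)]
  data.frame(kind = kind, auc_pc = auc,
             peak_latency_s = times[p] - onset_s,
             peak_pa = trace$samples[p] - i0,
             stringsAsFactors = FALSE)
}

#' Normalize OFF-trial PSC charge to ON-trial charge, per cell
#'
#' For every cell, `normalized = mean(AUC over OFF trials) / mean(AUC over
#' ON trials)`; 1 means no difference, > 1 means larger currents on
#' population-OFF trials.
#'
#' @param psc `data.frame` with `cell_id`, `trial_id`, `auc_pc` (one row per
#'   trial per cell).
#' @param classification Data frame with `trial_id` and `is_on`.
#' @return `data.frame` with `cell_id`, `mean_on_pc`, `mean_off_pc`,
#'   `normalized`.
#' @export
normalize_off_to_on <- function(psc, classification) {
  m <- merge(psc, classification[, c("trial_id", "is_on")], by = "trial_id")
  out <- do.call(rbind, lapply(split(m, m$cell_id), function(d) {
    on <- d$auc_pc[d$is_on]
    off <- d$auc_pc[!d$is_on]
    if (!length(on) || !length(off))
      stop(sprintf("cell %s lacks ON or OFF trials", d$cell_id[1L]))
    if (mean(on) == 0)
      stop(sprintf("cell %s has zero mean ON charge", d$cell_id[1L]))
    data.frame(cell_id = d$cell_id[1L], mean_on_pc = mean(on),
               mean_off_pc = mean(off), normalized = mean(off) / mean(on),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Membrane-potential distribution and UP-state bimodality
#'
#' Characterizes the post-stimulus membrane potential of a current-clamped
#' cell: the trace is decimated from the acquisition rate to
#' `target_rate_hz` (anti-aliased), action potentials (samples above
#' `spike_threshold_mv` plus a +/- 2 ms neighborhood) and the stimulus
#' artifact window are excised, a two-component Gaussian mixture is fitted
#' to the retained samples, and Ashman's
#' `D = sqrt(2) * |mu1 - mu2| / sqrt(s1^2 + s2^2)` scores the separation;
#' `D > 2` flags a bimodal (UP-state) distribution.
#'
#' @param trace An [ephys_trace()] with modality `"Vm"` at >= 2 kHz.
#' @param onset_s Stimulus onset on the trace clock.
#' @param window_s Analysis window after onset; should cover comparable
#'   spans of the UP state and the basal potential.
#' @param spike_threshold_mv Spike excision threshold (default -20 mV).
#' @param blank_s Stimulus-artifact blanking after onset (default 10 ms).
#' @param target_rate_hz Analysis sampling rate (default 2000 Hz).
#' @param exclude_spikes Set FALSE to skip spike excision (diagnostics).
#' @return An object of class `vm_distribution`: retained samples, histogram
#'   (0.5 mV bins), mixture means/SDs/weights (means ordered), `ashman_d`,
#'   `bimodal`.
#' @export
vm_distribution <- function(trace, onset_s, window_s = 1,
                            spike_threshold_mv = -20, blank_s = 0.01,
                            target_rate_hz = 2000, exclude_spikes = TRUE) {
  stopifnot(inherits(trace, "ephys_trace"))
  if (trace$modality != "Vm") stop("vm_distribution expects a Vm trace")
  fs <- trace$sampling_rate_hz
  fac <- max(1L, round(fs / target_rate_hz))
  x <- if (fac > 1L) signal::decimate(trace$samples, fac) else trace$samples
  fs2 <- fs / fac
  times <- trace$t0_s + (seq_along(x) - 1L) / fs2
  keep <- times >= onset_s & times < onset_s + window_s
  keep <- keep & !(times >= onset_s & times < onset_s + blank_s)
  if (exclude_spikes) {
    spk <- which(x > spike_threshold_mv)
    if (length(spk)) {
      halo <- round(0.002 * fs2)
      bad <- unique(unlist(lapply(spk, function(i)
        max(1L, i - halo):min(length(x), i + halo))))
      keep[bad] <- FALSE
    }
  }
  v <- x[keep]
  if (length(v) < 0.5 * fs2)
    stop("analysis window too short (< 0.5 s of retained samples)")
  fit <- Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  mu <- as.numeric(fit$parameters$mean)
  sg <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sg) == 1L) sg <- rep(sg, 2L)
  w <- as.numeric(fit$parameters$pro)
  o <- order(mu)
  d <- sqrt(2) * abs(diff(mu)) / sqrt(sum(sg^2))
  br <- seq(floor(min(v) / 0.5) * 0.5, ceiling(max(v) / 0.5) * 0.5, by = 0.5)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  structure(list(samples_mv = v,
                 histogram = data.frame(mid_mv = h$mids, count = h$counts),
                 means_mv = mu[o], sds_mv = sg[o], weights = w[o],
                 ashman_d = d, bimodal = d > 2),
            class = "vm_distribution")
}

#' @export
print.vm_distribution <- function(x, ...) {
  cat(sprintf(
    "<vm_distribution> components %.2f / %.2f mV (w = %.2f/%.2f), D = %.2f -> %s\n",
    x$means_mv[1L], x$means_mv[2L], x$weights[1L], x$weights[2L], x$ashman_d,
    if (x$bimodal) "bimodal" else "unimodal"))
  invisible(x)
}
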