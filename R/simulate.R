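#' Difference-of-exponentials indicator kernel
#'
#' `k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)` for `t >= 0`, normalized
#' to unit peak; 0 for `t < 0`.
#'
#' @param t Times in seconds (relative to event onset).
#' @param tau_rise,tau_decay Time constants in seconds
#'   (`tau_decay > tau_rise > 0`).
#' @return Kernel values, peak 1.
#' @export
dexp_kernel <- function(t, tau_rise, tau_decay) {
  if (tau_decay <= tau_rise || tau_rise <= 0)
    stop("need tau_decay > tau_rise > 0")
  t_star <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_star / tau_decay) - exp(-t_star / tau_rise)
  out <- ifelse(t >= 0, (exp(-t / tau_decay) - exp(-t / tau_rise)) / peak, 0)
  out
}

#' Parameters of the gating generative model
#'
#' Phenomenological parameters encoding the three core effects the generator
#' emulates: (1) trial-level Bernoulli gating of the population cortical
#' response with a logistic level dependence, (2) thalamic cells responding
#' on every trial but with larger peak-latency jitter on population-OFF
#' trials, and (3) larger thalamic (MGB) IPSC charge on OFF trials while
#' cortical PSCs vanish on OFF trials. Amplitudes are phenomenological, not
#' biophysical.
#'
#' @param s50 Logistic gating midpoint, dB SPL (tones) or uA (electrical).
#' @param k Logistic slope parameter, same unit as the level.
#' @param a_on ON-trial response amplitude, % delta-f/f (OFF amplitude is 0).
#' @param noise_sd_pct Sensor noise SD on the delta-f/f scale, % (white,
#'   Gaussian per pixel/sample).
#' @param baseline_counts Positive fluorescence baseline, counts.
#' @param ca_tau_rise_s,ca_tau_decay_s Calcium kernel time constants (s).
#' @param fa_tau_rise_s,fa_tau_decay_s FA kernel time constants (s).
#' @param cortical_latency_s Onset-to-event latency of the cortical
#'   population response (s).
#' @param latency_mu_s Thalamic cell mean event latency (s). Calcium peak
#'   latencies are long on the indicator timescale; the default keeps the
#'   whole jitter distribution inside the slice search window.
#' @param sigma_on_s,sigma_off_s Thalamic latency jitter SD on ON / OFF
#'   trials (s); `sigma_off_s > sigma_on_s`. Both exceed the 10 Hz frame
#'   period so that the jitter is resolvable in sampled peak latencies.
#' @param rho MGB IPSC OFF/ON charge ratio (>= 1).
#' @param phi Fraction of MGB cells whose OFF-trial IPSCs arrive earlier.
#' @param early_lead_s Lead of those early OFF-trial IPSCs (s).
#' @param psc_amp_pa IPSC peak amplitude (pA; EPSCs use the negative).
#' @param psc_tau_s PSC decay time constant (s).
#' @param psc_latency_mu_s,psc_latency_sd_s PSC onset latency mean / SD (s).
#' @param psc_noise_sd_pa Voltage-clamp noise SD (pA).
#' @param vm_rest_mv,vm_plateau_mv Resting and UP-state plateau potential
#'   (mV; plateau > rest).
#' @param plateau_dur_s UP-state plateau duration (s).
#' @param spike_rate_hz Poisson rate of action potentials on the plateau.
#' @param vm_noise_sd_mv Membrane-potential noise SD (mV).
#' @param lfp_amp_mv ON-trial LFP deflection amplitude (mV).
#' @param lfp_noise_sd_mv LFP background noise SD (mV).
#' @param img_hw Widefield frame size (H, W) in px.
#' @param blob_center_px,blob_sigma_px Response-blob center and SD (px).
#' @param first_trial_on Force the first trial of a run ON (the generator is
#'   memoryless by default).
#' @return A list of class `gating_params`.
#' @export
gating_params <- function(s50 = 55, k = 5,
                          a_on = 10, noise_sd_pct = 1, baseline_counts = 100,
                          ca_tau_rise_s = 0.05, ca_tau_decay_s = 0.6,
                          fa_tau_rise_s = 0.5, fa_tau_decay_s = 2.5,
                          cortical_latency_s = 0.1,
                          latency_mu_s = 1, sigma_on_s = 0.15,
                          sigma_off_s = 0.3,
                          rho = 1.5, phi = 0.5, early_lead_s = 0.02,
                          psc_amp_pa = 200, psc_tau_s = 0.05,
                          psc_latency_mu_s = 0.05, psc_latency_sd_s = 0.005,
                          psc_noise_sd_pa = 5,
                          vm_rest_mv = -65, vm_plateau_mv = -50,
                          plateau_dur_s = 0.5, spike_rate_hz = 20,
                          vm_noise_sd_mv = 2,
                          lfp_amp_mv = 0.5, lfp_noise_sd_mv = 0.02,
                          img_hw = c(40, 40), blob_center_px = c(20, 20),
                          blob_sigma_px = 5, first_trial_on = FALSE) {
  p <- as.list(environment())
  if (p$k == 0) stop("logistic slope k must be nonzero")
  if (p$sigma_off_s <= p$sigma_on_s || p$sigma_on_s <= 0)
    stop("need sigma_off_s > sigma_on_s > 0")
  if (p$rho < 1) stop("rho must be >= 1")
  if (p$ca_tau_decay_s <= p$ca_tau_rise_s ||
      p$fa_tau_decay_s <= p$fa_tau_rise_s)
    stop("kernel decay must exceed rise")
  if (p$vm_plateau_mv <= p$vm_rest_mv) stop("plateau must exceed rest")
  if (p$phi < 0 || p$phi > 1) stop("phi must lie in [0, 1]")
  class(p) <- "gating_params"
  p
}

#' Probability of a population-ON response at a stimulus level
#'
#' Logistic gating curve `p = 1 / (1 + exp(-(level - s50) / k))`, strictly
#' increasing in the level.
#'
#' @param level Stimulus level(s), finite.
#' @param params A [gating_params()].
#' @return Probabilities in (0, 1).
#' @export
p_on <- function(level, params = gating_params()) {
  if (any(!is.finite(level))) stop("level must be finite")
  1 / (1 + exp(-(level - params$s50) / params$k))
}

#' Simulate a full gated experiment
#'
#' Draws per-trial gate states `gate ~ Bernoulli(p_on(level))` and renders
#' the cortical population calcium trace of every trial (raw counts at
#' 10 Hz, 2 s pre-stimulus baseline): an indicator transient of amplitude
#' `a_on` on ON trials, baseline plus noise only on OFF trials. Identical
#' `(params, seed)` give identical output. Other modalities are rendered
#' from the returned gates by [simulate_widefield()],
#' [simulate_cell_traces()], [simulate_lfp()], [simulate_psc()] and
#' [simulate_vm()].
#'
#' @param params A [gating_params()].
#' @param n_trials Trials per level (>= 1).
#' @param levels Stimulus levels (dB SPL or uA).
#' @param seed Integer seed.
#' @param channel `"calcium"` (10 Hz) or `"FA"` (4 Hz) cortical signal.
#' @param pre_s,post_s Seconds of trace before/after stimulus onset.
#' @return List: `protocols` ([trial_protocol()]), `cortical`
#'   ([trace_set()] of raw counts, onset at time 0), `truth` (`data.frame`
#'   `trial_id`, `level`, `gate`), `params`, `seed`.
#' @export
simulate_experiment <- function(params = gating_params(), n_trials = 40,
                                levels = 37, seed = 1,
                                channel = c("calcium", "FA"),
                                pre_s = 2, post_s = 3) {
  channel <- match.arg(channel)
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(seed)
  rate <- if (channel == "calcium") 10 else 4
  taus <- if (channel == "calcium")
    c(params$ca_tau_rise_s, params$ca_tau_decay_s)
  else c(params$fa_tau_rise_s, params$fa_tau_decay_s)
  lv <- rep(levels, each = n_trials)
  n <- length(lv)
  gate <- stats::rbinom(n, 1L, p_on(lv, params)) == 1L
  if (params$first_trial_on) gate[1L] <- TRUE
  times <- seq(-pre_s, post_s - 1 / rate, by = 1 / rate)
  b <- params$baseline_counts
  noise_sd <- params$noise_sd_pct / 100 * b
  traces <- matrix(stats::rnorm(n * length(times), b, noise_sd), nrow = n)
  amp <- params$a_on / 100 * b
  for (i in which(gate)) {
    traces[i, ] <- traces[i, ] +
      amp * dexp_kernel(times - params$cortical_latency_s, taus[1L], taus[2L])
  }
  traces <- pmax(traces, 0)
  # trace clock: t = 0 at stimulus onset (t0_s = -pre_s)
  protocols <- trial_protocol(seq_len(n), stim_onset_s = 0,
                              stim_kind = if (max(lv) > 100) "electrical"
                                          else "tone",
                              level = lv, response_window_s = 1)
  list(protocols = protocols,
       cortical = trace_set(traces, rate, unit = "counts", t0_s = -pre_s,
                            ids = seq_len(n)),
       truth = data.frame(trial_id = seq_len(n), level = lv, gate = gate),
       params = params, seed = seed)
}

#' Simulate a widefield stack for one trial
#'
#' A constant positive baseline with i.i.d. Gaussian sensor noise per pixel;
#' on ON trials a 2-D Gaussian response blob is added whose temporal profile
#' is the indicator kernel scaled to peak `a_on` % delta-f/f at the blob
#' center.
#'
#' @param gate Logical: population-ON trial?
#' @param params A [gating_params()].
#' @param seed Integer seed.
#' @param channel `"calcium"` or `"FA"`.
#' @param pre_s,post_s Seconds before/after stimulus onset (onset at
#'   `t = 0`).
#' @return An [imaging_stack()] with `t0_s = -pre_s`.
#' @export
simulate_widefield <- function(gate, params = gating_params(), seed = 1,
                               channel = c("calcium", "FA"),
                               pre_s = 2, post_s = 3) {
  channel <- match.arg(channel)
  set.seed(seed)
  rate <- if (channel == "calcium") 10 else 4
  taus <- if (channel == "calcium")
    c(params$ca_tau_rise_s, params$ca_tau_decay_s)
  else c(params$fa_tau_rise_s, params$fa_tau_decay_s)
  times <- seq(-pre_s, post_s - 1 / rate, by = 1 / rate)
  h <- params$img_hw[1L]; w <- params$img_hw[2L]
  b <- params$baseline_counts
  noise_sd <- params$noise_sd_pct / 100 * b
  frames <- array(stats::rnorm(length(times) * h * w, b, noise_sd),
                  c(length(times), h, w))
  if (isTRUE(gate)) {
    rr <- matrix(0:(h - 1L), h, w)
    cc <- matrix(0:(w - 1L), h, w, byrow = TRUE)
    blob <- exp(-((rr - params$blob_center_px[1L])^2 +
                    (cc - params$blob_center_px[2L])^2) /
                  (2 * params$blob_sigma_px^2))
    prof <- dexp_kernel(times - params$cortical_latency_s, taus[1L],
                        taus[2L]) * params$a_on / 100 * b
    for (i in seq_along(times))
      frames[i, , ] <- frames[i, , ] + prof[i] * blob
  }
  imaging_stack(pmax(frames, 0), rate, channel, t0_s = -pre_s)
}

#' Simulate per-cell calcium traces across trials
#'
#' Thalamic (`"MGB"`) cells fire one event on every trial at
#' `latency_mu_s + N(0, sigma_state^2)` (truncated to the response window),
#' with `sigma_state = sigma_on_s` on ON trials and `sigma_off_s` on OFF
#' trials. Cortical layer-4 cells (`"cortexL4"`) are additionally gated:
#' silent on OFF trials.
#'
#' @param gate Logical vector of per-trial gate states.
#' @param n_cells Number of cells (>= 1).
#' @param params A [gating_params()].
#' @param seed Integer seed.
#' @param site `"MGB"` or `"cortexL4"`.
#' @param pre_s,post_s Trace extent around the onset (s); 10 Hz calcium.
#' @return List: `traces` (nested list `[[cell]][[trial]]` of raw-count
#'   vectors packaged as a [trace_set()] each... see Details), `events`
#'   (`data.frame` `cell_id`, `trial_id`, `event_time_s`, NA when silent),
#'   `rate_hz`, `t0_s`.
#' @details `traces[[cell]]` is a [trace_set()] whose rows are trials (raw
#'   counts); feed rows through [dff_trace()] or the whole structure through
#'   [latency_table()] via [cell_dff_traces()].
#' @export
simulate_cell_traces <- function(gate, n_cells, params = gating_params(),
                                 seed = 1, site = c("MGB", "cortexL4"),
                                 pre_s = 2, post_s = 3) {
  site <- match.arg(site)
  if (n_cells < 1) stop("n_cells must be >= 1")
  set.seed(seed)
  rate <- 10
  times <- seq(-pre_s, post_s - 1 / rate, by = 1 / rate)
  b <- params$baseline_counts
  noise_sd <- params$noise_sd_pct / 100 * b
  amp <- params$a_on / 100 * b
  n_tr <- length(gate)
  traces <- vector("list", n_cells)
  events <- list()
  for (ci in seq_len(n_cells)) {
    m <- matrix(stats::rnorm(n_tr * length(times), b, noise_sd), nrow = n_tr)
    ev <- rep(NA_real_, n_tr)
    for (ti in seq_len(n_tr)) {
      silent <- site == "cortexL4" && !gate[ti]
      if (!silent) {
        sg <- if (gate[ti]) params$sigma_on_s else params$sigma_off_s
        ev[ti] <- min(max(params$latency_mu_s + stats::rnorm(1L, 0, sg),
                          0.05), post_s - 0.8)
        m[ti, ] <- m[ti, ] + amp * dexp_kernel(times - ev[ti],
                                               params$ca_tau_rise_s,
                                               params$ca_tau_decay_s)
      }
    }
    traces[[ci]] <- trace_set(pmax(m, 0), rate, unit = "counts",
                              t0_s = -pre_s, ids = seq_len(n_tr))
    events[[ci]] <- data.frame(cell_id = sprintf("cell%03d", ci),
                               trial_id = seq_len(n_tr), event_time_s = ev)
  }
  names(traces) <- sprintf("cell%03d", seq_len(n_cells))
  list(traces = traces, events = do.call(rbind, events), rate_hz = rate,
       t0_s = -pre_s)
}

#' Convert simulated cell traces to per-cell delta-f/f traces
#'
#' @param sim Output of [simulate_cell_traces()].
#' @param baseline_len_s Baseline length for [dff_trace()].
#' @return Nested list `[[cell]][[trial]]` of [dff_trace()] objects, ready
#'   for [latency_table()].
#' @export
cell_dff_traces <- function(sim, baseline_len_s = 2) {
  lapply(sim$traces, function(ts) {
    out <- lapply(seq_len(nrow(ts$traces)), function(i)
      dff_trace(as.numeric(ts$traces[i, ]), ts$sampling_rate_hz,
                stim_onset_s = 0, baseline_len_s = baseline_len_s,
                t0_s = ts$t0_s))
    names(out) <- rownames(ts$traces)
    out
  })
}

#' Simulate a local field potential trace for one trial
#'
#' 20 kHz trace: AR(1) plus white background noise, a brief stimulus
#' artifact at the onset on every trial, and on ON trials a damped
#' post-stimulus deflection (negative-going, exponentially decaying).
#'
#' @param gate Logical: population-ON trial?
#' @param params A [gating_params()].
#' @param seed Integer seed.
#' @param pre_s,post_s Trace extent around onset (s).
#' @return An [ephys_trace()] (modality LFP, `t0_s = -pre_s`).
#' @export
simulate_lfp <- function(gate, params = gating_params(), seed = 1,
                         pre_s = 1, post_s = 2) {
  set.seed(seed)
  fs <- 20000
  times <- seq(-pre_s, post_s - 1 / fs, by = 1 / fs)
  n <- length(times)
  ar <- stats::filter(stats::rnorm(n, 0, params$lfp_noise_sd_mv / 4),
                      0.995, method = "recursive")
  x <- stats::rnorm(n, 0, params$lfp_noise_sd_mv) + as.numeric(ar) * 0.1
  art <- times >= 0 & times < 0.002
  x[art] <- x[art] + 2          # stimulus artifact, all trials
  if (isTRUE(gate)) {
    tt <- times - 0.02
    defl <- ifelse(tt >= 0, -params$lfp_amp_mv * exp(-tt / 0.1) *
                     (1 - exp(-tt / 0.005)), 0)
    x <- x + defl
  }
  ephys_trace(x, fs, "LFP", t0_s = -pre_s)
}

#' Simulate a voltage-clamped postsynaptic current for one cell and trial
#'
#' Exponential-decay synaptic events on a noisy baseline. MGB IPSCs occur on
#' every trial, with charge scaled by `rho` on OFF trials; MGB EPSC charge
#' is state-independent; cortical layer-4 PSCs occur on ON trials only. For
#' the fraction `phi` of MGB cells flagged `early_cell`, OFF-trial IPSC
#' onsets are advanced by `early_lead_s`.
#'
#' @param gate Logical: population-ON trial?
#' @param site `"MGB"` or `"cortexL4"`.
#' @param kind `"IPSC"` (holding +10 mV) or `"EPSC"` (holding -60 mV).
#' @param params A [gating_params()].
#' @param seed Integer seed.
#' @param early_cell Is this one of the early-IPSC MGB cells? (Draw it once
#'   per cell with probability `phi`.)
#' @param pre_s,post_s Trace extent around onset (s); 20 kHz.
#' @return An [ephys_trace()] (modality PSC).
#' @export
simulate_psc <- function(gate, site = c("MGB", "cortexL4"),
                         kind = c("IPSC", "EPSC"), params = gating_params(),
                         seed = 1, early_cell = FALSE,
                         pre_s = 1, post_s = 1.5) {
  site <- match.arg(site)
  kind <- match.arg(kind)
  set.seed(seed)
  fs <- 20000
  times <- seq(-pre_s, post_s - 1 / fs, by = 1 / fs)
  x <- stats::rnorm(length(times), 0, params$psc_noise_sd_pa)
  holding <- if (kind == "IPSC") 10 else -60
  present <- if (site == "cortexL4") isTRUE(gate) else TRUE
  if (present) {
    amp <- params$psc_amp_pa
    if (kind == "EPSC") amp <- -amp
    if (site == "MGB" && kind == "IPSC" && !isTRUE(gate)) amp <- amp * params$rho
    lat <- max(params$psc_latency_mu_s +
                 stats::rnorm(1L, 0, params$psc_latency_sd_s), 0.002)
    if (site == "MGB" && kind == "IPSC" && !isTRUE(gate) && early_cell)
      lat <- max(lat - params$early_lead_s, 0.002)
    tt <- times - lat
    x <- x + ifelse(tt >= 0, amp * exp(-tt / params$psc_tau_s), 0)
  }
  ephys_trace(x, fs, "PSC", holding_mv = holding, t0_s = -pre_s)
}

#' Simulate a current-clamp membrane-potential trace for one trial
#'
#' Resting potential plus Gaussian noise; on ON trials a depolarized plateau
#' (`vm_plateau_mv` for `plateau_dur_s`, starting 50 ms after the onset)
#' carrying Poisson action potentials (stereotyped 2 ms triangular waveforms
#' peaking at +10 mV).
#'
#' @param gate Logical: population-ON trial?
#' @param params A [gating_params()].
#' @param seed Integer seed.
#' @param pre_s,post_s Trace extent around onset (s); 20 kHz.
#' @return An [ephys_trace()] (modality Vm).
#' @export
simulate_vm <- function(gate, params = gating_params(), seed = 1,
                        pre_s = 1, post_s = 1.5) {
  set.seed(seed)
  fs <- 20000
  times <- seq(-pre_s, post_s - 1 / fs, by = 1 / fs)
  x <- stats::rnorm(length(times), params$vm_rest_mv, params$vm_noise_sd_mv)
  if (isTRUE(gate)) {
    up <- times >= 0.05 & times < 0.05 + params$plateau_dur_s
    x[up] <- x[up] + (params$vm_plateau_mv - params$vm_rest_mv)
    n_spk <- stats::rpois(1L, params$spike_rate_hz * params$plateau_dur_s)
    if (n_spk > 0) {
      spk_t <- sort(stats::runif(n_spk, 0.05, 0.05 + params$plateau_dur_s))
      half <- round(0.001 * fs)
      wave <- (10 - params$vm_plateau_mv) *
        (1 - abs(seq(-half, half)) / half)
      for (st in spk_t) {
        i0 <- which.min(abs(times - st))
        idx <- (i0 - half):(i0 + half)
        ok <- idx >= 1L & idx <= length(x)
        x[idx[ok]] <- x[idx[ok]] + wave[ok]
      }
    }
  }
  ephys_trace(x, fs, "Vm", t0_s = -pre_s)
}
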