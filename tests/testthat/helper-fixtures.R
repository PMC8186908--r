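# Shared fixture builders. Everything is generated in code; no stored data.

constant_stack <- function(value = 7, t = 3, h = 4, w = 4, rate = 10,
                           channel = "calcium") {
  imaging_stack(array(value, c(t, h, w)), rate, channel)
}

# raw trace with a known double-exponential transient riding on a baseline
transient_trace <- function(amp_frac = 0.3, f0 = 100, rate = 10, pre_s = 2,
                            post_s = 3, latency = 0.1, tau = c(0.05, 0.6)) {
  times <- seq(-pre_s, post_s - 1 / rate, by = 1 / rate)
  list(raw = f0 * (1 + amp_frac * dexp_kernel(times - latency, tau[1],
                                              tau[2])),
       times = times, rate = rate)
}

# crafted dff_trace with fully controlled values (baseline alternates +/- sd)
crafted_dff <- function(window_values, baseline_sd = 1, rate = 10,
                        baseline_n = 20) {
  base <- rep(c(-baseline_sd, baseline_sd), length.out = baseline_n)
  vals <- c(base, window_values)
  sdb <- stats::sd(base)
  structure(list(values = vals,
                 times_s = (-baseline_n:(length(window_values) - 1L)) / rate,
                 sampling_rate_hz = rate, stim_onset_s = 0,
                 baseline_window_s = c(-baseline_n / rate, 0),
                 f0 = 100, baseline_mean = mean(base), baseline_sd = sdb,
                 source_roi = NA_character_),
            class = "dff_trace")
}
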