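test_that("LFP conditioning has unit DC gain, a 60 Hz notch, and a flat
           passband below the corner", {
  fs <- 20000
  t <- seq(0, 2, by = 1 / fs)
  ctr <- 15000:25000  # steady state, away from filter edge transients

  dc <- filter_lfp(ephys_trace(rep(5, length(t)), fs, "LFP"))
  expect_equal(mean(dc$samples[ctr]) / 5, 1, tolerance = 0.01)

  s60 <- sin(2 * pi * 60 * t)
  f60 <- filter_lfp(ephys_trace(s60, fs, "LFP"))
  atten_db <- 20 * log10(stats::sd(f60$samples[ctr]) / stats::sd(s60[ctr]))
  expect_lt(atten_db, -20)

  s10 <- sin(2 * pi * 10 * t)
  f10 <- filter_lfp(ephys_trace(s10, fs, "LFP"))
  expect_equal(stats::sd(f10$samples[ctr]) / stats::sd(s10[ctr]), 1,
               tolerance = 0.05)

  # idempotence up to 1% RMS on LFP-band (sub-corner) content
  xb <- sin(2 * pi * 5 * t) + 0.7 * sin(2 * pi * 25 * t) +
    0.5 * sin(2 * pi * 40 * t)
  f1 <- filter_lfp(ephys_trace(xb, fs, "LFP"))
  f2 <- filter_lfp(f1)
  rel <- sqrt(mean((f2$samples[ctr] - f1$samples[ctr])^2)) /
    sqrt(mean(f1$samples[ctr]^2))
  expect_lt(rel, 0.01)

  expect_error(filter_lfp(ephys_trace(rep(0, 100), 1000, "LFP")),
               "too low")
  expect_error(filter_lfp(ephys_trace(rep(0, 100), fs, "Vm")), "LFP")
})

test_that("LFP response calls agree with the gate and ignore the artifact", {
  # flat trace with an artifact spike inside the blanking window -> OFF
  fs <- 20000
  t <- seq(-1, 1, by = 1 / fs)
  set.seed(72)
  x <- stats::rnorm(length(t), 0, 0.02)
  x[t >= 0 & t < 0.002] <- 2
  call <- lfp_response_call(ephys_trace(x, fs, "LFP", t0_s = -1), 0)
  expect_false(call$is_on)

  # generator ON deflection -> ON; OFF -> OFF
  on <- lfp_response_call(filter_lfp(simulate_lfp(TRUE, seed = 73)), 0)
  off <- lfp_response_call(filter_lfp(simulate_lfp(FALSE, seed = 74)), 0)
  expect_true(on$is_on)
  expect_false(off$is_on)

  # joint trials: >= 95% agreement with the imaging classification
  gates <- rep(c(TRUE, FALSE), 10)
  agree <- vapply(seq_along(gates), function(i) {
    lfp <- filter_lfp(simulate_lfp(gates[i], seed = 750 + i))
    lfp_response_call(lfp, 0)$is_on == gates[i]
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("PSC charge matches closed forms and is linear", {
  fs <- 20000
  tt <- seq(-1, 1.5, by = 1 / fs)

  # zero trace -> zero charge
  z <- psc_charge(ephys_trace(rep(0, length(tt)), fs, "PSC",
                              holding_mv = 10, t0_s = -1), 0)
  expect_equal(z$auc_pc, 0)

  # 100 pA rectangle lasting 0.5 s -> 50 pC
  rect <- ifelse(tt >= 0.05 & tt < 0.55, 100, 0)
  r <- psc_charge(ephys_trace(rect, fs, "PSC", holding_mv = 10, t0_s = -1),
                  0)
  expect_equal(r$auc_pc, 50, tolerance = 1e-3)

  # A exp(-t / tau): charge A tau = 10 pC within 0.1%
  ex <- ifelse(tt >= 0.02, 200 * exp(-(tt - 0.02) / 0.05), 0)
  e <- psc_charge(ephys_trace(ex, fs, "PSC", holding_mv = 10, t0_s = -1), 0)
  expect_equal(e$auc_pc, 10, tolerance = 1e-3)
  expect_equal(e$peak_latency_s, 0.02, tolerance = 1e-3)

  # linearity in the current; invariance to a baseline shift
  e3 <- psc_charge(ephys_trace(3 * ex, fs, "PSC", holding_mv = 10,
                               t0_s = -1), 0)
  expect_equal(e3$auc_pc, 3 * e$auc_pc, tolerance = 1e-9)
  esh <- psc_charge(ephys_trace(ex + 40, fs, "PSC", holding_mv = 10,
                                t0_s = -1), 0)
  expect_equal(esh$auc_pc, e$auc_pc, tolerance = 1e-6)

  # EPSC at -60 mV: extremum is the minimum
  ep <- psc_charge(ephys_trace(-ex, fs, "PSC", holding_mv = -60, t0_s = -1),
                   0)
  expect_equal(ep$kind, "EPSC")
  expect_equal(ep$peak_latency_s, 0.02, tolerance = 1e-3)
  expect_lt(ep$peak_pa, 0)

  expect_error(psc_charge(ephys_trace(rep(0, 30000), fs, "PSC",
                                      holding_mv = 10, t0_s = -1), 0,
                          window_s = 1),
               "exceeds")
})

test_that("OFF/ON charge normalization recovers the generator ratio", {
  gates <- rep(c(TRUE, FALSE), each = 3)
  cls <- data.frame(trial_id = seq_along(gates), is_on = gates)
  run_cells <- function(rho, n_cells, seed0) {
    p <- gating_params(rho = rho)
    do.call(rbind, lapply(seq_len(n_cells), function(ci)
      do.call(rbind, lapply(seq_along(gates), function(ti)
        cbind(data.frame(cell_id = ci, trial_id = ti),
              psc_charge(simulate_psc(gates[ti], "MGB", "IPSC", p,
                                      seed = seed0 + ci * 37L + ti), 0))))))
  }
  nm <- normalize_off_to_on(run_cells(1.5, 8, 8000), cls)
  ci <- stats::t.test(nm$normalized, mu = 1.5)$conf.int
  expect_gte(1.5, ci[1])
  expect_lte(1.5, ci[2])
  expect_equal(mean(nm$normalized), 1.5, tolerance = 0.05)

  # rho = 1 -> normalized ~ 1
  nm1 <- normalize_off_to_on(run_cells(1, 6, 9000), cls)
  expect_equal(mean(nm1$normalized), 1, tolerance = 0.05)

  # cortical IPSCs vanish on OFF trials -> normalized << 1
  psc_cx <- do.call(rbind, lapply(1:4, function(ci)
    do.call(rbind, lapply(seq_along(gates), function(ti)
      cbind(data.frame(cell_id = ci, trial_id = ti),
            psc_charge(simulate_psc(gates[ti], "cortexL4", "IPSC",
                                    seed = 9500 + ci * 37L + ti), 0))))))
  nm_cx <- normalize_off_to_on(psc_cx, cls)
  expect_lt(mean(nm_cx$normalized), 0.3)

  # permuting the ON/OFF labels of a rho = 1 cell keeps expectation at 1
  psc1 <- run_cells(1, 1, 9900)
  set.seed(77)
  vals <- vapply(1:50, function(i) {
    perm <- sample(gates)
    normalize_off_to_on(psc1, data.frame(trial_id = seq_along(gates),
                                         is_on = perm))$normalized
  }, numeric(1))
  expect_equal(mean(vals), 1, tolerance = 0.05)

  expect_error(normalize_off_to_on(psc1[gates, ], cls), "lacks ON or OFF")
})

test_that("Vm bimodality analysis recovers rest and plateau", {
  # unimodal rest -> D below 2
  off <- vm_distribution(simulate_vm(FALSE, seed = 81), 0, 1)
  expect_false(off$bimodal)

  # crafted half/half mixture at -65 / -50 mV, sigma 2: means within 1 mV
  set.seed(82)
  v <- c(stats::rnorm(4000, -65, 2), stats::rnorm(4000, -50, 2))
  mix <- vm_distribution(ephys_trace(v[sample(length(v))], 2000, "Vm"),
                         0, 2, blank_s = 0)
  expect_true(mix$bimodal)
  expect_lt(abs(mix$means_mv[1] - -65), 1)
  expect_lt(abs(mix$means_mv[2] - -50), 1)
  expect_equal(sum(mix$weights), 1, tolerance = 1e-6)

  # generator ON trial: bimodal after spike excision, means near
  # rest/plateau; without excision the upper mean shifts upward
  on <- vm_distribution(simulate_vm(TRUE, seed = 83), 0, 1)
  expect_true(on$bimodal)
  expect_lt(abs(on$means_mv[1] - -65), 1)
  expect_lt(abs(on$means_mv[2] - -50), 1)
  on_spk <- vm_distribution(simulate_vm(TRUE, seed = 83), 0, 1,
                            exclude_spikes = FALSE)
  expect_gt(on_spk$means_mv[2], on$means_mv[2])

  # spike rate 0: identical with and without excision
  p0 <- gating_params(spike_rate_hz = 0)
  a <- vm_distribution(simulate_vm(TRUE, p0, seed = 84), 0, 1)
  b <- vm_distribution(simulate_vm(TRUE, p0, seed = 84), 0, 1,
                       exclude_spikes = FALSE)
  expect_equal(a$means_mv, b$means_mv)

  expect_error(vm_distribution(simulate_vm(TRUE, seed = 85), 0, 0.3),
               "too short")
})

test_that("decimation preserves sub-300 Hz content", {
  fs <- 20000
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 40 * t) + 0.5 * sin(2 * pi * 150 * t)
  dec <- signal::decimate(x, 10)
  t2 <- seq(0, 1, by = 10 / fs)[seq_along(dec)]
  ref <- sin(2 * pi * 40 * t2) + 0.5 * sin(2 * pi * 150 * t2)
  ctr <- 200:1800
  rel <- sqrt(mean((dec[ctr] - ref[ctr])^2)) / sqrt(mean(ref[ctr]^2))
  expect_lt(rel, 0.02)
})
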