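test_that("roi_mean_trace equals the brute-force pixel loop", {
  # constant stack -> constant trace
  expect_equal(roi_mean_trace(constant_stack(7),
                              roi("r", "region",
                                  mask = matrix(TRUE, 4, 4))),
               rep(7, 3))

  # two-pixel ROI over values 4 and 6 -> 5
  fr <- array(4, c(2, 3, 3)); fr[, 2, 3] <- 6
  m <- matrix(FALSE, 3, 3); m[2, 2] <- TRUE; m[2, 3] <- TRUE
  fr[, 2, 2] <- 4
  st <- imaging_stack(fr, 10, "calcium")
  expect_equal(roi_mean_trace(st, roi("p", "region", mask = m)), c(5, 5))

  # random stack: exact agreement with an explicit per-frame loop
  set.seed(2)
  fr <- array(stats::runif(6 * 10 * 12) * 100, c(6, 10, 12))
  st <- imaging_stack(fr, 10, "calcium")
  mask <- matrix(stats::runif(120) < 0.3, 10, 12)
  mask[1, 1] <- TRUE
  got <- roi_mean_trace(st, roi("r", "region", mask = mask))
  oracle <- vapply(1:6, function(t) mean(fr[t, , ][mask]), numeric(1))
  expect_identical(got, oracle)

  expect_error(roi_mean_trace(st, roi("e", "cell", center = c(5, 11),
                                      radii = c(3, 3))),
               "beyond the frame")
})

test_that("dff_trace implements the 2 s pre-stimulus baseline formula", {
  # constant trace -> all-zero dff
  d <- dff_trace(rep(50, 50), 10, stim_onset_s = 0, t0_s = -2)
  expect_equal(d$values, rep(0, 50))
  expect_equal(d$f0, 50)

  # baseline 10 then step to 12 -> 20%
  raw <- c(rep(10, 20), rep(12, 10))
  d <- dff_trace(raw, 10, stim_onset_s = 0, t0_s = -2)
  expect_equal(unique(d$values[21:30]), 20)

  # double-exponential transient of amplitude 0.3 f0: peak dff equals
  # 100 * 0.3 * kernel max, against direct kernel evaluation
  tt <- transient_trace(amp_frac = 0.3)
  d <- dff_trace(tt$raw, tt$rate, stim_onset_s = 0, t0_s = -2)
  oracle <- 100 * 0.3 * max(dexp_kernel(tt$times - 0.1, 0.05, 0.6))
  expect_equal(max(d$values), oracle, tolerance = 1e-9)

  expect_error(dff_trace(rep(10, 5), 10, stim_onset_s = 0, t0_s = -0.1),
               "insufficient")
  expect_error(dff_trace(rep(0, 50), 10, stim_onset_s = 0, t0_s = -2),
               "positive")
})

test_that("dff is invariant to count scaling and zero for constant stacks", {
  tt <- transient_trace()
  d1 <- dff_trace(tt$raw, 10, 0, t0_s = -2)
  d2 <- dff_trace(7.3 * tt$raw, 10, 0, t0_s = -2)
  expect_equal(d1$values, d2$values, tolerance = 1e-12)
  expect_equal(d1$baseline_sd, d2$baseline_sd, tolerance = 1e-12)

  st <- constant_stack(123, t = 60, rate = 10)
  mp <- two_condition_dff_map(st, st, trial_protocol(1, 5, "tone", 37,
                                                     condition = "C1"))
  expect_equal(mp$values, matrix(0, 4, 4))
})

test_that("two-condition map isolates the response window, C1 - C0", {
  fr0 <- array(100, c(100, 6, 6))
  fr1 <- fr0
  fr1[51:60, 2, 5] <- 110   # 1 s window at the 5th second, 10 Hz
  s0 <- imaging_stack(fr0, 10, "calcium")
  s1 <- imaging_stack(fr1, 10, "calcium")
  pr <- trial_protocol(1, 5, "tone", 37, condition = "C1")
  mp <- two_condition_dff_map(s0, s1, pr)
  expect_equal(mp$values[2, 5], 10)
  expect_equal(sum(mp$values != 0), 1)

  # antisymmetry under condition swap
  set.seed(3)
  sa <- imaging_stack(array(stats::runif(100 * 6 * 6) * 50 + 50,
                            c(100, 6, 6)), 10, "calcium")
  sb <- imaging_stack(array(stats::runif(100 * 6 * 6) * 50 + 50,
                            c(100, 6, 6)), 10, "calcium")
  m1 <- two_condition_dff_map(sa, sb, pr)
  m2 <- two_condition_dff_map(sb, sa, pr)
  expect_equal(m1$values, -m2$values, tolerance = 1e-12)

  expect_error(two_condition_dff_map(s0, constant_stack(1, t = 100, h = 3,
                                                        w = 3, rate = 10),
                                     pr),
               "equal geometry")
})

test_that("widefield generator blob centroid is recovered within 1 px", {
  set.seed(7)
  # average the maps of several ON trials, as in the in vivo design
  maps <- lapply(1:8, function(i) {
    s1 <- simulate_widefield(TRUE, seed = 100 + i, pre_s = 5, post_s = 5)
    s0 <- simulate_widefield(FALSE, seed = 200 + i, pre_s = 5, post_s = 5)
    # re-stamp clocks so each stack is one 10 s condition
    s1$t0_s <- 0; s0$t0_s <- 0
    two_condition_dff_map(s0, s1, trial_protocol(1, 5, "tone", 37,
                                                 condition = "C1"))$values
  })
  avg <- Reduce(`+`, maps) / length(maps)
  w <- pmax(avg, 0)
  rr <- matrix(0:(nrow(w) - 1), nrow(w), ncol(w))
  cc <- matrix(0:(ncol(w) - 1), nrow(w), ncol(w), byrow = TRUE)
  centroid <- c(sum(rr * w), sum(cc * w)) / sum(w)
  expect_lt(max(abs(centroid - c(20, 20))), 1)
})

test_that("neuropil correction matches the mask-arithmetic oracle exactly", {
  set.seed(4)
  fr <- array(stats::runif(5 * 40 * 40) * 100 + 1, c(5, 40, 40))
  st <- imaging_stack(fr, 10, "calcium")
  cells <- list(roi("c1", "cell", center = c(10, 10), radii = c(3, 3)),
                roi("c2", "cell", center = c(15, 13), radii = c(2, 4)),
                roi("c3", "cell", center = c(28, 12), radii = c(3, 2)))
  got <- neuropil_corrected_trace(st, cells[[1]], cells)
  cm <- roi_mask(cells[[1]], c(40, 40))
  ann <- roi_mask(cells[[1]], c(40, 40), scale = 2.25)
  for (cc in cells) ann <- ann & !roi_mask(cc, c(40, 40))
  oracle <- vapply(1:5, function(t)
    mean(fr[t, , ][cm]) - 0.4 * mean(fr[t, , ][ann]), numeric(1))
  expect_identical(got, oracle)

  # zero background -> corrected equals the cell mean
  fr0 <- fr
  for (t in 1:5) { f <- fr0[t, , ]; f[!cm] <- 0; fr0[t, , ] <- f }
  st0 <- imaging_stack(fr0, 10, "calcium")
  got0 <- neuropil_corrected_trace(st0, cells[[1]], cells)
  expect_equal(got0, vapply(1:5, function(t) mean(fr0[t, , ][cm]),
                            numeric(1)))

  # subtraction_fraction 0 reduces to roi_mean_trace
  got_zero <- neuropil_corrected_trace(st, cells[[1]], cells,
                                       neuropil_config(subtraction_fraction
                                                       = 0))
  expect_equal(got_zero, roi_mean_trace(st, cells[[1]]))

  # arithmetic example: cell mean 50, background 10 -> 46
  frc <- array(10, c(2, 40, 40))
  for (t in 1:2) { f <- frc[t, , ]; f[cm] <- 50; frc[t, , ] <- f }
  stc <- imaging_stack(frc, 10, "calcium")
  expect_equal(neuropil_corrected_trace(stc, cells[[1]], cells[1]),
               c(46, 46))
})
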