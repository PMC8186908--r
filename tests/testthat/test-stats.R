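test_that("normality gate routes by the Lilliefors criterion", {
  set.seed(91)
  expect_equal(as.character(normality_gate(list(stats::rnorm(200)))),
               "parametric")
  expect_equal(as.character(normality_gate(list(stats::rexp(200)))),
               "nonparametric")
  # one bad group flips the route
  expect_equal(as.character(normality_gate(list(stats::rnorm(100),
                                                stats::rexp(200)))),
               "nonparametric")
  expect_error(normality_gate(list(c(1, 2))), "n >= 3")
  expect_error(normality_gate(list(rep(2, 10))), "zero SD")
  # tiny-n Monte Carlo fallback returns a usable route
  expect_true(as.character(normality_gate(list(c(0.1, 2.4, 1.1)))) %in%
                c("parametric", "nonparametric"))
})

test_that("paired t follows the closed form and is antisymmetric", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))  # d = {1,2,3}
  expect_equal(r$statistic, 2 * sqrt(3))
  expect_equal(r$df, 2)

  set.seed(92)
  a <- stats::rnorm(12); b <- stats::rnorm(12)
  expect_equal(paired_t(a, b)$statistic, -paired_t(b, a)$statistic)
  expect_equal(paired_t(a, b)$p_value, paired_t(b, a)$p_value)
  expect_error(paired_t(a, a), "zero-variance")
  expect_error(paired_t(a, b[1:5]), "equal length")
})

test_that("Wilcoxon exact p matches full sign enumeration for n <= 10", {
  set.seed(93)
  for (n in c(6, 8, 10)) {
    for (rep in 1:5) {
      a <- stats::rnorm(n)
      b <- stats::rnorm(n)
      got <- wilcoxon_signed_rank(a, b)
      d <- a - b
      r <- rank(abs(d))
      v_all <- vapply(0:(2^n - 1), function(m) {
        s <- as.integer(intToBits(m))[1:n]
        sum(r[s == 1])
      }, numeric(1))
      v_obs <- sum(r[d > 0])
      p_enum <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
      expect_equal(got$statistic, v_obs)
      expect_equal(got$p_value, p_enum, tolerance = 1e-12)
    }
  }

  # symmetric differences -> p = 1
  expect_equal(wilcoxon_signed_rank(c(-1, 1, -2, 2), rep(0, 4))$p_value, 1)
  # all-positive differences, n = 6 -> smallest attainable p = 2/64
  expect_equal(wilcoxon_signed_rank(2 * (1:6), 1:6)$p_value, 2 / 64)
  # zeros are dropped
  expect_equal(wilcoxon_signed_rank(c(0, -1, 1, -2, 2) + c(5, 0, 0, 0, 0),
                                    c(5, 0, 0, 0, 0))$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")

  # ties route through the tie-corrected normal approximation
  tied <- wilcoxon_signed_rank(c(2, 2, -2, 3, 3, -3, 4, 4), rep(0, 8))
  expect_equal(tied$method, "normal approximation")
  expect_true(tied$p_value >= 0 && tied$p_value <= 1)
})

test_that("RM-ANOVA matches the sums-of-squares oracle and aov", {
  # all conditions identical -> F = 0
  m0 <- matrix(rep(c(1, 3, 5, 7), 3), 4, 3)
  expect_equal(rm_anova_bonferroni(m0)$statistic, 0)

  set.seed(94)
  m <- matrix(stats::rnorm(12, 10, 2), 4, 3)
  got <- rm_anova_bonferroni(m)
  # explicit decomposition, written independently of the implementation
  grand <- mean(m)
  ssc <- 0
  for (j in 1:3) ssc <- ssc + 4 * (mean(m[, j]) - grand)^2
  sss <- 0
  for (i in 1:4) sss <- sss + 3 * (mean(m[i, ]) - grand)^2
  sse <- 0
  for (i in 1:4) for (j in 1:3)
    sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
  f_oracle <- (ssc / 2) / (sse / 6)
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(got$df, c(2, 6))

  # cross-check against aov's Error(subject/condition) stratum
  df <- data.frame(y = as.vector(m), s = factor(rep(1:4, 3)),
                   c = factor(rep(1:3, each = 4)))
  av <- summary(stats::aov(y ~ c + Error(s / c), df))[[2]][[1]]
  expect_equal(got$statistic, av[["F value"]][1], tolerance = 1e-10)
  expect_equal(got$p_value, av[["Pr(>F)"]][1], tolerance = 1e-10)

  # F is invariant to condition relabeling
  expect_equal(rm_anova_bonferroni(m[, c(3, 1, 2)])$statistic,
               got$statistic)

  # Bonferroni adjustment is exactly min(1, m * p)
  expect_equal(got$posthoc$p_adj, pmin(1, 3 * got$posthoc$p_raw))

  mna <- m; mna[2, 2] <- NA
  expect_error(rm_anova_bonferroni(mna), "missing cells")
})

test_that("Kruskal-Wallis + Dunn matches the rank-sum formula", {
  # identical tied groups -> H = 0
  expect_equal(kruskal_dunn(list(a = c(1, 2, 3),
                                 b = c(1, 2, 3)))$statistic, 0)

  g <- list(a = c(1, 5, 8, 2), b = c(2, 9, 11), c = c(10, 12, 13, 6))
  got <- kruskal_dunn(g)
  # direct rank computation with tie correction
  x <- unlist(g)
  lab <- rep(names(g), lengths(g))
  r <- rank(x)
  n <- length(x)
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, lab, sum)^2 / tapply(r, lab, length)) - 3 * (n + 1)
  ties <- table(r)
  h_oracle <- h_raw / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(got$statistic, h_oracle, tolerance = 1e-12)
  expect_equal(got$statistic, unname(stats::kruskal.test(g)$statistic))

  # well-separated groups: the extreme pair is significant after Bonferroni
  sep <- kruskal_dunn(list(lo = c(1, 2, 3), hi = c(10, 11, 12)))
  expect_lt(sep$posthoc$p_adj[1], 0.05)

  expect_error(kruskal_dunn(list(1:5)), ">= 2 groups")
  expect_error(kruskal_dunn(list(a = 1:2, b = numeric())), "empty group")
})

test_that("log-linear OLS reports R^2, slope and slope p", {
  x <- c(50, 100, 150, 200, 300)
  y <- 2 + 3 * log10(x)
  r <- suppressWarnings(ols_loglinear(x, y))  # exact fit warns in summary.lm
  expect_equal(r$statistic, 1)
  expect_equal(r$slope, 3)

  set.seed(95)
  yn <- y + stats::rnorm(5, 0, 0.2)
  rn <- ols_loglinear(x, yn)
  lmref <- summary(stats::lm(yn ~ log10(x)))
  expect_equal(rn$statistic, lmref$r.squared)
  expect_equal(rn$p_value, lmref$coefficients[2, 4])

  expect_error(ols_loglinear(c(-1, 2, 3), 1:3), "positive")
  expect_error(ols_loglinear(rep(10, 4), 1:4), "zero variance")
})

test_that("null slope p-values are uniform for the log-linear fit", {
  set.seed(96)
  x <- rep(c(50, 100, 200, 400), each = 5)
  ps <- vapply(1:400, function(i)
    ols_loglinear(x, stats::rnorm(length(x)))$p_value, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.035)
})
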