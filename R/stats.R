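stats_result <- function(test_name, statistic, df, p_value, posthoc = NULL,
                         extra = NULL) {
  out <- c(list(test_name = test_name, statistic = statistic, df = df,
                p_value = p_value, posthoc = posthoc, alpha = 0.05), extra)
  class(out) <- "popgate_stats"
  out
}

#' @export
print.popgate_stats <- function(x, ...) {
  dfs <- if (length(x$df)) paste0("(", paste(x$df, collapse = ", "), ")")
         else ""
  cat(sprintf("%s: statistic%s = %.4g, p = %.4g\n", x$test_name, dfs,
              x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc (adjusted p):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

lilliefors_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Normality gate
#'
#' Routes an analysis to its parametric or non-parametric branch the way the
#' study design prescribes: every group is checked with a Lilliefors-style
#' Kolmogorov-Smirnov test (normal with estimated mean/SD) at alpha = 0.05;
#' the route is `"parametric"` iff all groups pass. `nortest::lillie.test`
#' supplies the p-value for n >= 5; for n of 3 or 4 (below its minimum) the
#' same D statistic is referred to a Monte Carlo null distribution.
#'
#' @param groups List of numeric vectors, each of length >= 3 with positive
#'   SD.
#' @param alpha Gate level (default 0.05).
#' @param mc_reps Monte Carlo replicates for the tiny-n fallback.
#' @return `"parametric"` or `"nonparametric"`, with per-group p-values in
#'   the `"p_values"` attribute.
#' @export
normality_gate <- function(groups, alpha = 0.05, mc_reps = 2000) {
  if (!is.list(groups)) groups <- list(groups)
  ps <- vapply(groups, function(g) {
    if (length(g) < 3L) stop("each group needs n >= 3")
    if (stats::sd(g) == 0) stop("degenerate group (zero SD)")
    if (length(g) >= 5L) return(nortest::lillie.test(g)$p.value)
    d <- lilliefors_d(g)
    null_d <- vapply(seq_len(mc_reps),
                     function(i) lilliefors_d(stats::rnorm(length(g))),
                     numeric(1L))
    mean(null_d >= d)
  }, numeric(1L))
  out <- if (all(ps > alpha)) "parametric" else "nonparametric"
  attr(out, "p_values") <- ps
  out
}

#' Paired t-test
#'
#' Two-sided paired-sample t-test on `d = a - b`, df = n - 1.
#'
#' @param a,b Equal-length numeric vectors (n >= 2).
#' @return A `popgate_stats` result (statistic t, df, two-sided p, plus the
#'   mean difference).
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("need n >= 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) stop("zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  stats_result("paired t-test", unname(tt$statistic), unname(tt$parameter),
               tt$p.value, extra = list(mean_diff = mean(d)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon convention); |d| are ranked with
#' average ranks and V is the positive-rank sum. For n <= 25 without tied
#' ranks the two-sided p is exact (signed-rank distribution, equivalent to
#' full 2^n enumeration); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Equal-length numeric vectors with >= 1 nonzero difference.
#' @return A `popgate_stats` result (statistic V, two-sided p; the `method`
#'   element records the branch taken).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (!n) stop("all differences are zero")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0L
  if (n <= 25L && !ties) {
    p <- min(1, 2 * min(stats::psignrank(v, n),
                        1 - stats::psignrank(v - 1, n)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  stats_result("paired Wilcoxon signed-rank test", v, n, p,
               extra = list(method = method))
}

#' One-way repeated-measures ANOVA with Bonferroni post hocs
#'
#' Classical subjects x conditions decomposition: F = MS_condition /
#' MS_error with df (k - 1, (k - 1)(n - 1)) and no sphericity correction
#' (matching how such designs are conventionally reported). Post hocs are
#' pairwise paired t-tests with Bonferroni adjustment
#' (`p_adj = min(1, m * p)`).
#'
#' @param m Complete numeric matrix, subjects in rows, conditions in columns
#'   (>= 2 each). Column names label the post hoc pairs.
#' @return A `popgate_stats` result (statistic F, df, p, `posthoc` table).
#' @export
rm_anova_bonferroni <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells: the design must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(k))
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_err == 0) {
    # degenerate decomposition: identical conditions give F = 0, an exact
    # condition effect with no residual gives F = Inf
    f <- if (ss_cond == 0) 0 else Inf
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
  }
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  pairs <- utils::combn(k, 2)
  nc <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(nc), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d <- m[, i1] - m[, i2]
    if (stats::sd(d) == 0) {
      tj <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      pj <- if (mean(d) == 0) 1 else 0
    } else {
      pt <- stats::t.test(m[, i1], m[, i2], paired = TRUE)
      tj <- unname(pt$statistic); pj <- pt$p.value
    }
    data.frame(pair = paste(colnames(m)[i1], "vs", colnames(m)[i2]),
               t = tj, p_raw = pj,
               p_adj = min(1, nc * pj), stringsAsFactors = FALSE)
  }))
  stats_result("repeated-measures ANOVA", f, c(df1, df2), p, posthoc)
}

#' Kruskal-Wallis test with Dunn post hocs
#'
#' Tie-corrected Kruskal-Wallis H (via [stats::kruskal.test()]) followed by
#' Dunn's pairwise z comparisons on the pooled ranks, with the usual tie
#' correction and Bonferroni adjustment of the two-sided p-values.
#'
#' @param groups Named list of >= 2 numeric vectors (total n >= 5).
#' @return A `popgate_stats` result (statistic H, df, p, `posthoc` table).
#' @export
kruskal_dunn <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  if (sum(lengths(groups)) < 5L) stop("total n must be >= 5")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n_tot <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n_tot - 1))
  pairs <- utils::combn(names(groups), 2)
  nc <- ncol(pairs)
  posthoc <- do.call(rbind, lapply(seq_len(nc), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    se <- sqrt((n_tot * (n_tot + 1) / 12 - tie_term) *
                 (1 / ni[[g1]] + 1 / ni[[g2]]))
    z <- (rbar[[g1]] - rbar[[g2]]) / se
    p_raw <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(g1, "vs", g2), z = z, p_raw = p_raw,
               p_adj = min(1, nc * p_raw), stringsAsFactors = FALSE)
  }))
  stats_result("Kruskal-Wallis test", unname(kw$statistic),
               unname(kw$parameter), kw$p.value, posthoc)
}

#' Log-linear fit of response amplitude on stimulus level
#'
#' Ordinary least squares of `y` on `log10(x)`, the relationship expected
#' between upstream (midbrain/thalamic) response amplitude and stimulating
#' current. Returns R-squared and the two-sided slope p-value.
#'
#' @param x Positive stimulus amplitudes (e.g. uA), n >= 3, non-constant.
#' @param y Response amplitudes (e.g. % delta-f/f).
#' @return A `popgate_stats` result (statistic R^2, slope, intercept,
#'   slope p).
#' @export
ols_loglinear <- function(x, y) {
  if (any(x <= 0)) stop("stimulus amplitudes must be positive")
  if (length(x) != length(y) || length(x) < 3L) stop("need n >= 3 pairs")
  lx <- log10(x)
  if (stats::var(lx) == 0) stop("zero variance in log10(x)")
  fit <- stats::lm(y ~ lx)
  sm <- summary(fit)
  stats_result("log-linear OLS", unname(sm$r.squared),
               unname(sm$df[2L]), unname(sm$coefficients[2L, 4L]),
               extra = list(slope = unname(stats::coef(fit)[2L]),
                            intercept = unname(stats::coef(fit)[1L]),
                            r_squared = unname(sm$r.squared)))
}

#' Recompute the printed test statistics from deposited source data
#'
#' Reruns the three headline statistics from the study's per-figure source
#' data, given a directory of CSV exports: the paired t on ON vs OFF
#' latency variances, the repeated-measures ANOVA of percent-ON by
#' stimulating current, and the log-linear R^2 of midbrain amplitude on
#' current. Expected files (CSV conversions of the deposited tables):
#' `latency_variance_pairs.csv` (columns `var_on`, `var_off`),
#' `percent_on_by_current.csv` (subjects x current-amplitude matrix), and
#' `amplitude_by_current.csv` (columns `current_ua`, `dff_pct`).
#'
#' @param dir Directory containing the CSV files.
#' @return Named list of `popgate_stats` results (`latency_t`,
#'   `percent_on_f`, `loglinear_r2`).
#' @export
reproduce_printed_stats <- function(dir) {
  need <- c("latency_variance_pairs.csv", "percent_on_by_current.csv",
            "amplitude_by_current.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing source-data files: ", paste(missing, collapse = ", "))
  pairs <- utils::read.csv(file.path(dir, "latency_variance_pairs.csv"))
  mat <- as.matrix(utils::read.csv(file.path(dir,
                                             "percent_on_by_current.csv")))
  amp <- utils::read.csv(file.path(dir, "amplitude_by_current.csv"))
  list(latency_t = paired_t(pairs$var_on, pairs$var_off),
       percent_on_f = rm_anova_bonferroni(mat),
       loglinear_r2 = ols_loglinear(amp$current_ua, amp$dff_pct))
}
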