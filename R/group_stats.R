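#' Bootstrap percentile confidence interval of the median
#'
#' Percentile method on `n_boot` seeded resamples with replacement
#' (2.5th/97.5th percentiles of the bootstrap median distribution at the
#' default 95% level).
#'
#' @param x Numeric values (n >= 2, NAs dropped).
#' @param n_boot Number of bootstrap resamples (default 50,000).
#' @param seed Optional seed; `NULL` uses the current stream.
#' @param conf Confidence level.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_median_ci <- function(x, n_boot = 50000, seed = NULL,
                                conf = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, n * n_boot, replace = TRUE)
  meds <- apply(matrix(x[idx], nrow = n), 2, stats::median)
  a <- (1 - conf) / 2
  q <- stats::quantile(meds, c(a, 1 - a), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Normality gate (Lilliefors test)
#'
#' Kolmogorov-Smirnov normality test with estimated mean and SD at
#' alpha = 0.05, used to route group comparisons to the parametric or the
#' rank-sum branch.  Fewer than 5 values, or a degenerate (zero-variance)
#' sample, is classed `"non_normal"` with a warning.
#'
#' @param x Numeric values.
#' @param alpha Significance level of the gate.
#' @return `"normal"` or `"non_normal"`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 5) {
    warning("fewer than 5 values: treating as non-normal")
    return("non_normal")
  }
  if (stats::sd(x) == 0) {
    warning("zero variance: treating as non-normal")
    return("non_normal")
  }
  p <- nortest::lillie.test(x)$p.value
  if (p >= alpha) "normal" else "non_normal"
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Reports the Mann-Whitney U statistic for `x` (rank sum of `x` minus its
#' minimum).  The p-value is exact (via the null Wilcoxon distribution) when
#' there are no ties and both groups have fewer than 50 observations;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   p-value.
#' @return List: `statistic` (U), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- length(unique(c(x, y))) < n1 + n2
  if (is.null(exact)) exact <- !ties && n1 < 50 && n2 < 50
  if (exact && ties) {
    warning("cannot compute exact p-value with ties; using normal approximation")
    exact <- FALSE
  }
  if (exact) {
    p <- if (u > n1 * n2 / 2)
      2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(u, n1, n2)
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tab <- table(r)
    sigma2 <- n1 * n2 / 12 *
      (n1 + n2 + 1 - sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- u - mu
    z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = u, p_value = p, method = method)
}

#' Compare a metric between the two groups
#'
#' The testing policy: each group's sample passes through the Lilliefors
#' normality gate; if both are normal the comparison delegates to Welch's
#' t-test (labelled `parametric`), otherwise — or when the gate is
#' bypassed — the two-sided Mann-Whitney rank-sum test is used.  Group
#' medians with 95% bootstrap CIs are always reported, along with the sign
#' of the treated-minus-control median difference.  Raw p-values are
#' reported (no multiplicity correction on this path).
#'
#' Note the nested design: sites within a rat are not independent, and this
#' site-level test does not model that (the delegated mixed-model route
#' would).
#'
#' @param values Numeric metric values, one per site.
#' @param group Group labels aligned with `values`; compared as
#'   `levels[2] - levels[1]` (default order `saline`, `vpa`).
#' @param metric Metric name for reporting.
#' @param gate Apply the normality gate (`FALSE` forces rank-sum).
#' @param n_boot,seed Bootstrap parameters for the median CIs (`ci = FALSE`
#'   skips them).
#' @param ci Compute bootstrap CIs.
#' @return Object of class `group_comparison`.
#' @export
compare_metric <- function(values, group, metric = "metric", gate = TRUE,
                           n_boot = 50000, seed = NULL, ci = TRUE) {
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- as.character(group)[keep]
  lev <- intersect(c("saline", "vpa"), unique(group))
  if (length(lev) < 2) lev <- sort(unique(group))
  if (length(lev) != 2) stop("need exactly two non-empty groups")
  g1 <- values[group == lev[1]]; g2 <- values[group == lev[2]]
  if (!length(g1) || !length(g2)) stop("one group is empty")
  if (!is.null(seed)) set.seed(seed)
  branch <- "rank_sum"
  if (gate) {
    nrm <- vapply(list(g1, g2), function(v)
      suppressWarnings(normality_gate(v)), character(1))
    if (all(nrm == "normal")) branch <- "parametric"
  }
  if (branch == "parametric") {
    tt <- stats::t.test(g2, g1)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    rs <- rank_sum_test(g1, g2)
    statistic <- rs$statistic
    p <- rs$p_value
  }
  med <- c(stats::median(g1), stats::median(g2))
  cis <- if (ci) list(bootstrap_median_ci(g1, n_boot),
                      bootstrap_median_ci(g2, n_boot))
         else list(c(lo = NA_real_, hi = NA_real_),
                   c(lo = NA_real_, hi = NA_real_))
  out <- list(metric = metric, groups = lev,
              n = c(length(g1), length(g2)), median = med,
              ci95 = cis, test = branch, statistic = statistic,
              p_value = p, direction = sign(med[2] - med[1]))
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  fmt_ci <- function(ci) if (anyNA(ci)) "" else
    sprintf(" (%.3g-%.3g)", ci[1], ci[2])
  cat(sprintf("%s: %s %.4g%s vs %s %.4g%s; %s p = %.4g (n = %d/%d)\n",
              x$metric,
              x$groups[1], x$median[1], fmt_ci(x$ci95[[1]]),
              x$groups[2], x$median[2], fmt_ci(x$ci95[[2]]),
              if (x$test == "rank_sum") "Mann-Whitney U" else "t-test",
              x$p_value, x$n[1], x$n[2]))
  invisible(x)
}
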