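# Statistical primitives shared by all screening stages. These are thin,
# contract-enforcing surfaces over the standard implementations in `stats`
# and `survival`; degenerate inputs are flagged rather than propagated as NaN.

#' Pearson (or Spearman) correlation with a two-sided p-value
#'
#' Computes the product-moment correlation between `x` and `y` and its
#' two-sided significance from the t transform `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom. A zero-variance input does not produce an
#' error or `NaN`: the result is returned with `degenerate = TRUE`, `r = 0`
#' and `p = 1`, so callers can treat non-informative vectors uniformly.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param method `"pearson"` (default) or `"spearman"` (Pearson on ranks).
#' @return An object of class `"correlation_result"`: a list with elements
#'   `r`, `p`, `n` and `degenerate`.
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(4, 3, 2, 1))  # r = -1, p = 0
#' @export
pearson_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d", length(x), length(y))
  n <- length(x)
  if (n < 3) stopf("correlation requires at least 3 observations, got %d", n)
  if (anyNA(x) || anyNA(y)) stopf("missing values in correlation input")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(structure(list(r = 0, p = 1, n = n, degenerate = TRUE),
                     class = "correlation_result"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "pearson"))
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1) 0 else ct$p.value
  structure(list(r = r, p = p, n = n, degenerate = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (x$degenerate) cat("correlation: degenerate (zero variance), n =", x$n, "\n")
  else cat(sprintf("correlation: r = %.4f, p = %.3g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Kaplan-Meier product-limit survival curve
#'
#' Product-limit estimate of the survival function under right-censoring,
#' reported at the distinct event times. Ties between deaths and censorings
#' at the same time are resolved events-first (the censored subject is still
#' in the risk set at that time), as in [survival::survfit()].
#'
#' @param times Non-negative follow-up times (days).
#' @param events Logical vector; `TRUE` = death observed, `FALSE` = censored.
#' @return An object of class `"km_curve"`: list with `times` (distinct event
#'   times, increasing), `survival` (estimate just after each event time),
#'   `at_risk` (risk-set size at each event time), and `n`.
#' @export
km_curve <- function(times, events) {
  if (length(times) == 0) stopf("empty survival input")
  if (length(times) != length(events)) stopf("times/events length mismatch")
  if (any(times < 0)) stopf("negative survival time")
  events <- as.logical(events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  structure(list(times = fit$time[keep],
                 survival = fit$surv[keep],
                 at_risk = fit$n.risk[keep],
                 n = length(times)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank statistic: at each distinct event time the
#' observed minus expected events in group 1 are accumulated with the
#' hypergeometric variance; `chi2 = (sum(O-E))^2 / sum(V)` is referred to a
#' chi-square distribution with 1 df. Computed via [survival::survdiff()].
#' With zero observed events the test is undefined; a degenerate result with
#' `p = 1` is returned instead of an error so permutation loops stay total.
#'
#' @param times Non-negative follow-up times.
#' @param events Logical event indicators.
#' @param labels Two-level grouping vector (coerced to factor).
#' @return An object of class `"logrank_result"`: list with `chi2`, `p`,
#'   `n1`, `n2`, `degenerate`.
#' @export
logrank_test <- function(times, events, labels) {
  if (length(unique(c(length(times), length(events), length(labels)))) != 1)
    stopf("times/events/labels length mismatch")
  g <- factor(labels)
  if (nlevels(g) != 2) stopf("log-rank requires exactly two groups, got %d", nlevels(g))
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 == 0 || n2 == 0) stopf("empty group in log-rank test")
  events <- as.logical(events)
  if (!any(events)) {
    return(structure(list(chi2 = 0, p = 1, n1 = n1, n2 = n2, degenerate = TRUE),
                     class = "logrank_result"))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chi2 <- unname(sd$chisq)
  structure(list(chi2 = chi2,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 n1 = n1, n2 = n2, degenerate = FALSE),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4f, p = %.3g (n1 = %d, n2 = %d)%s\n",
              x$chi2, x$p, x$n1, x$n2,
              if (x$degenerate) " [degenerate: no events]" else ""))
  invisible(x)
}

#' Two-sided Mann-Whitney rank-sum p-value
#'
#' Two-sided Mann-Whitney U test p-value with tie correction, used by the
#' expression-abundance balance filter. Exact for small tie-free samples,
#' normal approximation with tie correction otherwise
#' (see [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param alternative Passed through; default two-sided.
#' @return The p-value (a number in `[0, 1]`).
#' @export
ranksum_test <- function(a, b, alternative = "two.sided") {
  if (length(a) < 2 || length(b) < 2) stopf("rank-sum test requires >= 2 values per group")
  suppressWarnings(stats::wilcox.test(a, b, alternative = alternative))$p.value
}

#' Bonferroni family-wise significance threshold
#'
#' @param m Number of tests in the family (positive integer).
#' @param alpha Family-wise error rate, in (0, 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(7509, 0.05)  # 6.66e-06
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) stopf("m must be a positive integer")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  alpha / m
}
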