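# Independent oracles used to check the package's statistics and search.
# These deliberately re-derive everything from first principles (textbook
# formulas, exhaustive enumeration) and never call the package's code paths.

# Pearson r and two-sided p straight from the covariance formula and the
# t transform, written without cor()/cor.test().
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# Product-limit estimator accumulated event time by event time; censored
# subjects leave the risk set after their censoring time (events-first ties).
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events]))
  surv <- numeric(length(ut)); risk <- integer(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at <- sum(times >= ut[i])
    d <- sum(events & times == ut[i])
    s <- s * (1 - d / at)
    surv[i] <- s; risk[i] <- at
  }
  list(times = ut, survival = surv, at_risk = risk)
}

# Two-group log-rank by direct accumulation of observed minus expected
# events with the hypergeometric variance at each distinct event time.
oracle_logrank <- function(times, events, g) {
  g <- as.integer(factor(g))
  ut <- sort(unique(times[events]))
  OE <- 0; V <- 0
  for (t in ut) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(events & times == t); d1 <- sum(events & times == t & g == 1)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(chi2 = 0, p = 1))
  chi2 <- OE^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled (tie-free) values to the two groups.
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  idx <- utils::combn(length(pooled), na)
  U_all <- apply(idx, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  mu <- na * length(b) / 2
  mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-12)
}

# Step-by-step replay of the greedy acceptance rule, independent of the
# compiled kernel: recomputes the subgroup correlation with cor() at every
# candidate and applies the stated reject test.
oracle_greedy <- function(x, y, init, ord, criterion = "corr_and_p") {
  corp <- function(ii) {
    if (length(ii) < 3) return(c(0, 1))
    r <- suppressWarnings(stats::cor(x[ii], y[ii]))
    if (is.na(r)) return(c(0, 1))
    if (abs(r) >= 1) return(c(r, 0))
    t <- r * sqrt((length(ii) - 2) / (1 - r^2))
    c(r, 2 * stats::pt(-abs(t), length(ii) - 2))
  }
  g1 <- init
  st <- corp(g1)
  for (k in ord) {
    tmp <- corp(c(g1, k))
    r_drops <- abs(st[1]) - abs(tmp[1]) > 1e-12
    reject <- if (criterion == "corr_only") r_drops
              else r_drops && st[2] < tmp[2]
    if (!reject) { g1 <- c(g1, k); st <- tmp }
  }
  list(group1 = sort(g1), r = st[1], p = st[2])
}

# Bayes-optimal planted-subgroup assignment for the synthetic mixture:
# planted (mir, gene) bivariate normal with correlation -rho, complement
# independent; standardized scale. Gives the information-theoretic ceiling
# for recovery.
oracle_bayes_group <- function(mir, gene, rho) {
  x <- as.numeric(scale(mir)); y <- as.numeric(scale(gene))
  llr <- -0.5 * log(1 - rho^2) -
    (x^2 + 2 * rho * x * y + y^2) / (2 * (1 - rho^2)) + (x^2 + y^2) / 2
  which(llr > 0)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
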