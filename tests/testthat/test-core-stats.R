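# Statistical primitives against independent oracles and their contracts.

test_that("pearson_with_p matches the direct-formula oracle and handles extremes", {
  # perfect anti-correlation
  res <- pearson_with_p(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(res$r, -1)
  expect_equal(res$p, 0)
  expect_false(res$degenerate)

  # zero-variance input is flagged, not propagated
  deg <- pearson_with_p(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  # direct-formula oracle on a fixed small case
  x <- c(2, 4, 5, 6, 8); y <- c(1, 3, 2, 5, 4)
  o <- oracle_pearson(x, y)
  res <- pearson_with_p(x, y)
  expect_equal(res$r, o$r, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)

  # and on seeded random instances
  for (s in 1:25) {
    set.seed(s)
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    o <- oracle_pearson(x, y); res <- pearson_with_p(x, y)
    expect_equal(res$r, o$r, tolerance = 1e-10)
    expect_equal(res$p, o$p, tolerance = 1e-10)
  }

  expect_error(pearson_with_p(1:3, 1:4), "length mismatch")
  expect_error(pearson_with_p(1:2, 2:1), "at least 3")
})

test_that("pearson_with_p is symmetric, affine-invariant and sign-flips under negation", {
  for (s in 1:20) {
    set.seed(100 + s)
    x <- rnorm(12); y <- rnorm(12)
    a <- pearson_with_p(x, y)
    expect_equal(pearson_with_p(y, x)$r, a$r, tolerance = 1e-12)
    b <- pearson_with_p(2.5 * x + 3, y)
    expect_equal(b$r, a$r, tolerance = 1e-12)
    expect_equal(b$p, a$p, tolerance = 1e-12)
    expect_equal(pearson_with_p(-x, y)$r, -a$r, tolerance = 1e-12)
  }
})

test_that("spearman option equals Pearson on ranks", {
  set.seed(5)
  x <- rnorm(15); y <- rnorm(15)
  sp <- pearson_with_p(x, y, method = "spearman")
  expect_equal(sp$r, unname(cor(x, y, method = "spearman")), tolerance = 1e-12)
})

test_that("km_curve is the product-limit estimator with events-first ties", {
  # four events at distinct times, no censoring
  km <- km_curve(c(10, 20, 30, 40), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$at_risk, c(4, 3, 2, 1))

  # all censored: no event times, curve stays at 1
  km <- km_curve(c(5, 8, 12), c(FALSE, FALSE, FALSE))
  expect_length(km$times, 0)

  # hand-computed mixed table (6 subjects, censor tied with event at t = 8)
  km <- km_curve(c(5, 8, 8, 12, 15, 20),
                 c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(km$times, c(5, 8, 12))
  expect_equal(km$survival, c(5 / 6, 5 / 6 * 4 / 5, 5 / 6 * 4 / 5 * 2 / 3),
               tolerance = 1e-12)
  expect_equal(km$at_risk, c(6, 5, 3))

  # random instances against the hand oracle; survival non-increasing
  for (s in 1:20) {
    set.seed(200 + s)
    n <- sample(4:12, 1)
    tm <- sample(1:10, n, replace = TRUE)
    ev <- runif(n) < 0.6
    if (!any(ev)) next
    km <- km_curve(tm, ev)
    o <- oracle_km(tm, ev)
    expect_equal(km$times, o$times)
    expect_equal(km$survival, o$survival, tolerance = 1e-12)
    expect_equal(km$at_risk, as.integer(o$at_risk))
    expect_true(all(diff(km$survival) <= 1e-12))
  }

  expect_error(km_curve(numeric(0), logical(0)), "empty")
  expect_error(km_curve(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("km_curve equals the empirical survival function without censoring", {
  set.seed(33)
  tm <- sample(1:50, 20, replace = TRUE)
  km <- km_curve(tm, rep(TRUE, 20))
  for (i in seq_along(km$times))
    expect_equal(km$survival[i], mean(tm > km$times[i]), tolerance = 1e-12)
})

test_that("logrank_test agrees with the textbook oracle and honors symmetry", {
  # two groups with identical survival experience
  tm <- c(5, 10, 15, 5, 10, 15); ev <- rep(TRUE, 6)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(tm, ev, g)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)

  # zero events: degenerate, p = 1
  lr <- logrank_test(c(5, 10), c(FALSE, FALSE), c("a", "b"))
  expect_true(lr$degenerate)
  expect_equal(lr$p, 1)

  # random small instances vs oracle; label-swap invariance
  for (s in 1:40) {
    set.seed(300 + s)
    n <- sample(6:12, 1)
    tm <- sample(1:8, n, replace = TRUE)
    ev <- runif(n) < 0.7
    g <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
    if (!any(ev)) next
    lr <- logrank_test(tm, ev, g)
    o <- oracle_logrank(tm, ev, g)
    expect_equal(lr$chi2, o$chi2, tolerance = 1e-10)
    expect_equal(lr$p, o$p, tolerance = 1e-10)
    sw <- logrank_test(tm, ev, 3 - g)
    expect_equal(sw$chi2, lr$chi2, tolerance = 1e-10)
  }

  expect_error(logrank_test(c(1, 2), c(TRUE, TRUE), c("a", "a")), "two groups")
})

test_that("ranksum_test matches exact enumeration and detects separation", {
  a <- c(1.2, 3.4, 2.2, 4.1)
  expect_equal(ranksum_test(a, a), 1, tolerance = 1e-9)
  expect_lt(ranksum_test(rep(0, 5), rep(10, 5)), 0.01)

  for (s in 1:25) {
    set.seed(400 + s)
    na <- sample(2:5, 1); nb <- sample(2:6, 1)
    v <- sample(seq(0.1, 10, by = 0.1), na + nb)  # tie-free
    a <- v[seq_len(na)]; b <- v[-seq_len(na)]
    expect_equal(ranksum_test(a, b), oracle_ranksum_exact(a, b),
                 tolerance = 1e-10)
  }

  expect_error(ranksum_test(1, c(1, 2)), ">= 2")
})

test_that("bonferroni_threshold is alpha / m", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(20, 0.05), 0.0025)
  expect_error(bonferroni_threshold(0, 0.05), "positive integer")
  expect_error(bonferroni_threshold(10, 1.5), "alpha")
})

test_that("null p-values are approximately uniform", {
  set.seed(42)
  p_corr <- replicate(300, pearson_with_p(rnorm(20), rnorm(20))$p)
  expect_gt(suppressWarnings(ks.test(p_corr, "punif"))$p.value, 0.01)

  p_lr <- replicate(300, {
    tm <- rexp(40, 1 / 100); ev <- runif(40) < 0.7
    logrank_test(tm, ev, rep(1:2, each = 20))$p
  })
  expect_gt(suppressWarnings(ks.test(p_lr, "punif"))$p.value, 0.01)
})
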