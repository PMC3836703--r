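# The greedy subgroup search and the pair-validity criterion.

test_that("perfectly anti-correlated samples all join Group 1", {
  x <- seq(1, 3, length.out = 12)
  y <- -x
  p <- greedy_partition(x, y, init_triple = c(1, 5, 9),
                        scan_order = setdiff(1:12, c(1, 5, 9)))
  expect_equal(p$group1, 1:12)
  expect_equal(p$corr1$r, -1)
  # every restart converges to the same set
  b1 <- best_partition(x, y, n_restarts = 1, seed = 7)
  b50 <- best_partition(x, y, n_restarts = 50, seed = 7)
  expect_equal(b1$group1, 1:12)
  expect_equal(b50$group1, b1$group1)
})

test_that("a sample that strictly weakens a perfect subgroup is rejected", {
  # n = 4: seed triple on an exact line, the one candidate off it
  x <- c(1, 2, 3, 2)
  y <- c(-1, -2, -3, 5)
  for (crit in c("corr_and_p", "corr_only")) {
    p <- greedy_partition(x, y, init_triple = 1:3, scan_order = 4,
                          criterion = crit)
    expect_equal(p$group1, 1:3)
    expect_equal(p$group2, 4L)
  }
})

test_that("a planted perfect subgroup seeded inside it is recovered exactly", {
  set.seed(9)
  n <- 12
  x <- rnorm(n)
  y <- -2 * x + 1          # exact line: r = -1 on any subset of the first 8
  y[9:12] <- y[9:12] + c(3, -4, 5, -6)  # off-line points strictly reduce |r|
  planted <- 1:8
  for (crit in c("corr_and_p", "corr_only")) {
    for (s in 1:5) {
      set.seed(s)
      init <- sample(planted, 3)
      ord <- sample(setdiff(1:n, init))
      p <- greedy_partition(x, y, init, ord, criterion = crit)
      expect_equal(p$group1, planted)
      expect_equal(p$corr1$r, -1)
    }
  }
})

test_that("the compiled kernel replays the stated acceptance rule exactly", {
  for (s in 1:30) {
    set.seed(500 + s)
    n <- sample(8:25, 1)
    x <- rnorm(n); y <- rnorm(n)
    init <- sample.int(n, 3)
    ord <- sample(setdiff(seq_len(n), init))
    for (crit in c("corr_and_p", "corr_only")) {
      p <- greedy_partition(x, y, init, ord, criterion = crit)
      o <- oracle_greedy(x, y, init, ord, criterion = crit)
      expect_equal(p$group1, o$group1)
      expect_equal(p$corr1$r, o$r, tolerance = 1e-10)
    }
  }
})

test_that("partition invariants hold on random inputs", {
  for (s in 1:25) {
    set.seed(600 + s)
    n <- sample(6:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    init <- sample.int(n, 3)
    ord <- sample(setdiff(seq_len(n), init))
    p <- greedy_partition(x, y, init, ord)
    expect_length(intersect(p$group1, p$group2), 0)
    expect_setequal(c(p$group1, p$group2), seq_len(n))
    expect_true(all(p$init_triple %in% p$group1))
    expect_gte(length(p$group1), 3)
    # stored corr1 equals a from-scratch recomputation
    re <- pearson_with_p(x[p$group1], y[p$group1])
    expect_equal(p$corr1$r, re$r, tolerance = 1e-12)
    expect_equal(p$corr1$p, re$p, tolerance = 1e-12)
  }
})

test_that("|r| is monotone non-decreasing along the literal-rule trace", {
  for (s in 1:20) {
    set.seed(700 + s)
    n <- sample(8:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    init <- sample.int(n, 3)
    ord <- sample(setdiff(seq_len(n), init))
    p <- greedy_partition(x, y, init, ord, criterion = "corr_only")
    expect_true(all(diff(abs(p$trace_r)) >= -1e-12))
  }
})

test_that("every default-rule acceptance improves |r| or significance", {
  for (s in 1:20) {
    set.seed(800 + s)
    n <- sample(10:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    p <- best_partition(x, y, n_restarts = 3, seed = s)
    dr <- diff(abs(p$trace_r)); dp <- diff(p$trace_p)
    expect_true(all(dr >= -1e-12 | dp <= 1e-12))
  }
})

test_that("greedy |r| never exceeds the best subset containing the seed (n <= 10)", {
  for (s in 1:8) {
    set.seed(900 + s)
    n <- 9
    x <- rnorm(n); y <- rnorm(n)
    init <- sample.int(n, 3)
    ord <- sample(setdiff(seq_len(n), init))
    p <- greedy_partition(x, y, init, ord, criterion = "corr_only")
    rest <- setdiff(seq_len(n), init)
    best <- 0
    for (k in 0:length(rest)) {
      for (extra in if (k == 0) list(integer(0)) else
                    asplit(utils::combn(rest, k), 2)) {
        sub <- c(init, extra)
        r <- suppressWarnings(cor(x[sub], y[sub]))
        if (!is.na(r)) best <- max(best, abs(r))
      }
    }
    expect_lte(abs(p$corr1$r), best + 1e-12)
  }
})

test_that("best_partition is deterministic given its seed", {
  set.seed(1); x <- rnorm(50); y <- rnorm(50)
  a <- best_partition(x, y, n_restarts = 10, seed = 123)
  b <- best_partition(x, y, n_restarts = 10, seed = 123)
  expect_identical(a$group1, b$group1)
  expect_identical(a$corr1$r, b$corr1$r)
  c <- best_partition(x, y, n_restarts = 10, seed = 124)
  expect_true(is.integer(c$group1))  # different seed still a valid partition
})

test_that("noise-free planted subgroups are recovered near-perfectly", {
  for (s in 1:10) {
    set.seed(s)
    n <- 100
    planted <- sort(sample.int(n, 50))
    mir <- rnorm(n); gene <- rnorm(n)
    gene[planted] <- -mir[planted]
    p <- best_partition(mir, gene, n_restarts = 10, seed = s)
    expect_gte(jaccard(p$group1, planted), 0.9)
  }
})

test_that("noisy planted recovery tracks the Bayes-optimal ceiling", {
  # at rho = 0.8 with matched marginals even the optimal likelihood-ratio
  # assignment misclassifies heavily; the greedy should stay within 75% of
  # that ceiling (it cannot beat it on average)
  gj <- numeric(10); bj <- numeric(10)
  for (s in 1:10) {
    d <- make_planted_pair(n = 120, fraction = 0.5, rho = 0.8, seed = s)
    p <- best_partition(d$mir, d$gene, n_restarts = 10, seed = s)
    gj[s] <- jaccard(p$group1, d$planted)
    bj[s] <- jaccard(oracle_bayes_group(d$mir, d$gene, 0.8), d$planted)
  }
  expect_gte(mean(gj), 0.75 * mean(bj))
  expect_lte(mean(gj), mean(bj) + 0.1)
})

test_that("pair_validity applies the sign, significance and size rules", {
  d <- make_planted_pair(n = 60, fraction = 0.5, rho = 0.95, seed = 3)
  p <- best_partition(d$mir, d$gene, n_restarts = 10, seed = 3)
  v <- pair_validity(p, alpha_corr = 0.05, min_group_size = 5)
  expect_true(v$group1_significant)
  expect_true(v$group1_negative)
  expect_equal(v$valid, v$group1_significant && v$group1_negative &&
                 v$group2_insignificant && v$sizes_ok)

  # positive correlation in Group 1 invalidates the pair
  pos <- p
  pos$corr1$r <- abs(pos$corr1$r)
  vpos <- pair_validity(pos, 0.05, 5)
  expect_false(vpos$group1_negative)
  expect_false(vpos$valid)

  # strong but insignificant correlation over a tiny group
  tiny <- p
  tiny$corr1 <- structure(list(r = -0.99, p = 0.08, n = 3, degenerate = FALSE),
                          class = "correlation_result")
  vtiny <- pair_validity(tiny, 0.05, 5)
  expect_false(vtiny$group1_significant)
  expect_false(vtiny$valid)
})

test_that("malformed seeds and scan orders are rejected", {
  x <- rnorm(10); y <- rnorm(10)
  expect_error(greedy_partition(x, y, c(1, 1, 2), 3:10), "distinct")
  expect_error(greedy_partition(x, y, 1:3, 5:10), "scan_order")
  expect_error(greedy_partition(x[1:3], y[1:3], 1:3, integer(0)), "at least 4")
  expect_error(best_partition(x, y, n_restarts = 0), "n_restarts")
})
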