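# Per-pair patient stratification: greedy growth of the anti-correlated
# subgroup (Group 1) from a random seed triple, restarts, and the validity
# criterion (significant negative correlation in Group 1, none in Group 2).

#' Grow the correlated subgroup for one miR-gene pair from a seed triple
#'
#' Starting from `Group 1 = init_triple`, candidates are visited once in
#' `scan_order`; each is tentatively added and the subgroup correlation
#' recomputed. Under the default rule (`criterion = "corr_and_p"`) a candidate
#' is sent to Group 2 only when admitting it would *both* shrink `|r|` *and*
#' raise the correlation p-value — a patient that preserves significance
#' (which improves with subgroup size at comparable `|r|`) keeps its place.
#' `criterion = "corr_only"` admits only candidates that do not strictly
#' decrease `|r|`, with ties admitted; `|r|` is then monotone non-decreasing
#' along the acceptance trace. With `converge = TRUE` rejected candidates are
#' re-scanned until a pass admits no one (the group only grows).
#'
#' @param mir_vec,gene_vec Expression of the miR and the gene across the same
#'   samples (length `n >= 4`).
#' @param init_triple Three distinct sample indices seeding Group 1.
#' @param scan_order Permutation of the remaining indices.
#' @param criterion Acceptance rule, see above.
#' @param converge Repeat scans until no candidate is admitted.
#' @param max_passes Safety cap on convergence passes.
#' @return An object of class `"pair_partition"`: list with `group1`, `group2`
#'   (sorted index vectors), `corr1`, `corr2` ([pearson_with_p()] results;
#'   `corr2` is degenerate-flagged when Group 2 has fewer than 3 samples),
#'   `init_triple`, `trace_r`, `trace_p`, `passes`, `n`.
#' @export
greedy_partition <- function(mir_vec, gene_vec, init_triple, scan_order,
                             criterion = c("corr_and_p", "corr_only"),
                             converge = FALSE, max_passes = 100L) {
  criterion <- match.arg(criterion)
  n <- length(mir_vec)
  if (length(gene_vec) != n) stopf("mir/gene vector length mismatch")
  if (n < 4) stopf("need at least 4 samples, got %d", n)
  init_triple <- as.integer(init_triple)
  scan_order <- as.integer(scan_order)
  if (length(init_triple) != 3 || anyDuplicated(init_triple))
    stopf("init_triple must be 3 distinct indices")
  if (!setequal(scan_order, setdiff(seq_len(n), init_triple)) ||
      anyDuplicated(scan_order))
    stopf("scan_order must cover exactly the non-seed indices")
  res <- .greedy_core(as.numeric(mir_vec), as.numeric(gene_vec),
                      init_triple - 1L, scan_order - 1L,
                      if (criterion == "corr_only") 1L else 0L,
                      converge, as.integer(max_passes))
  group1 <- sort(res$group1)
  group2 <- setdiff(seq_len(n), group1)
  corr1 <- pearson_with_p(mir_vec[group1], gene_vec[group1])
  corr2 <- if (length(group2) >= 3) {
    pearson_with_p(mir_vec[group2], gene_vec[group2])
  } else {
    structure(list(r = 0, p = 1, n = length(group2), degenerate = TRUE),
              class = "correlation_result")
  }
  structure(list(group1 = group1, group2 = group2,
                 corr1 = corr1, corr2 = corr2,
                 init_triple = sort(init_triple),
                 trace_r = res$trace_r, trace_p = res$trace_p,
                 passes = res$passes, criterion = criterion, n = n),
            class = "pair_partition")
}

#' Best greedy partition over random restarts
#'
#' Runs [greedy_partition()] from `n_restarts` independently drawn seed
#' triples and scan orders (all draws from one seeded generator, so the result
#' is fully deterministic given `seed`) and returns the best partition. Under
#' the default criterion "best" means smallest Group 1 correlation p-value;
#' under `"corr_only"` it means largest `|r|`. Ties are broken by larger
#' `|r|`, then larger Group 1, then lexicographically smallest Group 1.
#'
#' @inheritParams greedy_partition
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @return A `"pair_partition"` (see [greedy_partition()]).
#' @export
best_partition <- function(mir_vec, gene_vec, n_restarts = 10, seed = 1,
                           criterion = c("corr_and_p", "corr_only"),
                           converge = FALSE) {
  criterion <- match.arg(criterion)
  if (n_restarts < 1) stopf("n_restarts must be >= 1")
  n <- length(mir_vec)
  if (n < 4) stopf("need at least 4 samples, got %d", n)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_restarts)) {
      init <- sample.int(n, 3)
      ord <- setdiff(seq_len(n), init)
      if (length(ord) > 1) ord <- sample(ord)
      cand <- greedy_partition(mir_vec, gene_vec, init, ord,
                               criterion = criterion, converge = converge)
      if (is.null(best) || .partition_better(cand, best, criterion)) best <- cand
    }
    best
  })
}

# Restart comparison: significance-first under the default rule, |r|-first
# under the literal rule; deterministic tie-breaks.
.partition_better <- function(a, b, criterion) {
  key <- function(p) c(if (criterion == "corr_only") 0 else p$corr1$p,
                       -abs(p$corr1$r), -length(p$group1))
  ka <- key(a); kb <- key(b)
  for (i in seq_along(ka)) {
    if (ka[i] < kb[i]) return(TRUE)
    if (ka[i] > kb[i]) return(FALSE)
  }
  # full tie: lexicographically smallest group1
  d <- which(c(a$group1, Inf) != c(b$group1, Inf))[1]
  if (is.na(d)) return(FALSE)
  isTRUE(c(a$group1, Inf)[d] < c(b$group1, Inf)[d])
}

#' Validity of a pair's stratification
#'
#' A miR-gene pair is *valid* when Group 1 shows a significantly negative
#' correlation, Group 2 shows no significant correlation, and both groups
#' reach the minimum size. A Group 2 smaller than 3 samples cannot carry a
#' correlation; it fails the size requirement rather than the significance
#' one.
#'
#' @param partition A `"pair_partition"`.
#' @param alpha_corr Significance level for the within-group correlation.
#' @param min_group_size Minimum size of each group.
#' @return An object of class `"validity_flags"`: list with logicals
#'   `group1_significant`, `group1_negative`, `group2_insignificant`,
#'   `sizes_ok`, and `valid` (their conjunction).
#' @export
pair_validity <- function(partition, alpha_corr = 0.05, min_group_size = 10) {
  g1s <- !partition$corr1$degenerate && partition$corr1$p < alpha_corr
  g1n <- !partition$corr1$degenerate && partition$corr1$r < 0
  g2i <- !partition$corr2$degenerate && partition$corr2$p >= alpha_corr
  szs <- length(partition$group1) >= min_group_size &&
         length(partition$group2) >= min_group_size
  structure(list(group1_significant = g1s, group1_negative = g1n,
                 group2_insignificant = g2i, sizes_ok = szs,
                 valid = g1s && g1n && g2i && szs),
            class = "validity_flags")
}

#' @export
print.pair_partition <- function(x, ...) {
  cat(sprintf("pair partition (%s): |Group1| = %d, |Group2| = %d\n",
              x$criterion, length(x$group1), length(x$group2)))
  cat(sprintf("  Group1: r = %.4f, p = %.3g\n", x$corr1$r, x$corr1$p))
  if (x$corr2$degenerate) cat("  Group2: too small for a correlation\n")
  else cat(sprintf("  Group2: r = %.4f, p = %.3g\n", x$corr2$r, x$corr2$p))
  invisible(x)
}
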