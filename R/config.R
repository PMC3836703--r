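#' Screening configuration
#'
#' Collects the tunable parameters of the pair screen with validation.
#'
#' @param alpha_corr Significance level for within-group correlations
#'   (pair validity), default 0.05.
#' @param alpha_family Family-wise error rate for the Bonferroni-corrected
#'   log-rank screen, default 0.05.
#' @param alpha_filter Level of the abundance balance filter, default 0.05.
#' @param min_group_size Minimum size of each patient group, default 10.
#' @param n_restarts Random restarts of the greedy partition per pair,
#'   default 10.
#' @param n_fdr_iterations Survival-label permutations for the empirical FDR,
#'   default 1000.
#' @param seed Master seed; every random draw in the pipeline derives from it.
#' @param correlation_method `"pearson"` (default) or `"spearman"` (the
#'   screen then runs on globally rank-transformed expression vectors).
#' @param criterion Greedy acceptance rule, see [greedy_partition()].
#' @param converge Re-scan rejected patients until the subgroup stabilizes
#'   (default `FALSE`: one pass per restart).
#' @param filter_sided `"two.sided"` (default) or `"one.sided"` abundance
#'   filter (one-sided = flag only *lower* expression in a group).
#' @param pair_universe Optional two-column data.frame/matrix of
#'   (mir_id, gene_id) pairs to scan; default is the full cross product.
#' @return An object of class `"pipeline_config"` (a validated list).
#' @export
pipeline_config <- function(alpha_corr = 0.05, alpha_family = 0.05,
                            alpha_filter = 0.05, min_group_size = 10,
                            n_restarts = 10, n_fdr_iterations = 1000,
                            seed = 1,
                            correlation_method = c("pearson", "spearman"),
                            criterion = c("corr_and_p", "corr_only"),
                            converge = FALSE,
                            filter_sided = c("two.sided", "one.sided"),
                            pair_universe = NULL) {
  for (a in c(alpha_corr, alpha_family, alpha_filter))
    if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1)
      stopf("significance levels must be single numbers in (0, 1)")
  for (k in list(min_group_size, n_restarts, n_fdr_iterations))
    if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
      stopf("counts must be positive integers")
  if (!is.null(pair_universe)) {
    pair_universe <- as.data.frame(pair_universe, stringsAsFactors = FALSE)
    if (ncol(pair_universe) != 2) stopf("pair_universe must have two columns (mir, gene)")
    colnames(pair_universe) <- c("mir_id", "gene_id")
  }
  structure(list(alpha_corr = alpha_corr, alpha_family = alpha_family,
                 alpha_filter = alpha_filter,
                 min_group_size = as.integer(min_group_size),
                 n_restarts = as.integer(n_restarts),
                 n_fdr_iterations = as.integer(n_fdr_iterations),
                 seed = as.integer(seed),
                 correlation_method = match.arg(correlation_method),
                 criterion = match.arg(criterion),
                 converge = isTRUE(converge),
                 filter_sided = match.arg(filter_sided),
                 pair_universe = pair_universe),
            class = "pipeline_config")
}
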