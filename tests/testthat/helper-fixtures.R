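# Small fixtures built in code at test time.

# One miR-gene pair with a planted anti-correlated subgroup on a
# standardized scale; complement is independent noise with the same
# marginals.
make_planted_pair <- function(n = 120, fraction = 0.5, rho = 0.8, seed = 1) {
  set.seed(seed)
  planted <- sort(sample.int(n, round(fraction * n)))
  mir <- rnorm(n); gene <- rnorm(n)
  gene[planted] <- -rho * mir[planted] +
    sqrt(1 - rho^2) * rnorm(length(planted))
  list(mir = mir, gene = gene, planted = planted)
}

# Write a small expression matrix TSV from a character body (for loader
# edge cases) or from a matrix.
write_expr_tsv <- function(mat, path = tempfile(fileext = ".tsv")) {
  write_expression_matrix(mat, path)
  path
}

tiny_expr <- function(features, samples, seed = 1) {
  set.seed(seed)
  matrix(round(rnorm(length(features) * length(samples), 8, 1), 4),
         nrow = length(features), dimnames = list(features, samples))
}

tiny_clinical <- function(ids, seed = 1) {
  set.seed(seed)
  df <- data.frame(sample_id = ids,
                   time = round(rexp(length(ids), 1 / 300)),
                   event = runif(length(ids)) < 0.6,
                   stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}
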