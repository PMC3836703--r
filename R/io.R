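# Readers, writers and alignment for the tabular inputs: expression matrices
# (TSV, features x samples), the clinical table, and optional binding-site
# prediction tables. All values are assumed pre-normalized log-scale
# expression; no normalization is performed here.

#' Read a features-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds sample identifiers and
#' whose first column holds feature identifiers; the body must be numeric.
#' Rows containing any missing or non-numeric entry are dropped with a warning
#' (`on_missing = "drop"`, the default) or cause an error
#' (`on_missing = "fail"`). Correlations over silently varying sample subsets
#' are never allowed downstream, which is why incomplete rows cannot be kept.
#'
#' @param path Path to the TSV file.
#' @param on_missing `"drop"` or `"fail"`.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path, on_missing = c("drop", "fail")) {
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stopf("cannot read expression matrix: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stopf("expression matrix needs at least one sample column: %s", path)
  feat <- df[[1]]
  samp <- colnames(df)[-1]
  if (anyDuplicated(samp)) stopf("duplicate sample identifier in %s", path)
  if (anyDuplicated(feat)) stopf("duplicate feature identifier in %s", path)
  body <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  body <- matrix(body, nrow = nrow(df), dimnames = list(feat, samp))
  bad <- !stats::complete.cases(body) | apply(body, 1L, function(r) any(!is.finite(r)))
  if (any(bad)) {
    if (on_missing == "fail")
      stopf("%d row(s) with missing/non-numeric values in %s", sum(bad), path)
    warnf("dropped %d row(s) with missing/non-numeric values from %s", sum(bad), path)
    body <- body[!bad, , drop = FALSE]
  }
  if (nrow(body) == 0) stopf("zero usable feature rows in %s", path)
  body
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `feature`, one column
#' per sample. Values are written at full precision so a round-trip preserves
#' them to numeric-text accuracy.
#'
#' @param mat Numeric matrix with feature rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat),
                   format(mat, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Accepted vital-status encodings (lower-cased); unrecognized values error.
.event_synonyms <- c("1" = TRUE, "0" = FALSE,
                     "true" = TRUE, "false" = FALSE,
                     "deceased" = TRUE, "living" = FALSE,
                     "dead" = TRUE, "alive" = FALSE)

#' Read a clinical table (sample id, survival time, event status)
#'
#' Survival time is in days of follow-up; the event column accepts `1/0`,
#' `true/false`, `deceased/living` and `dead/alive` (case-insensitive), and is
#' normalized to logical (`TRUE` = death observed, `FALSE` = right-censored).
#' Any additional columns are retained as covariates. Rows with a missing
#' time or an empty event value are excluded with a warning reporting the
#' count; unrecognized non-missing event values are an error, never guessed.
#'
#' @param path Path to the TSV file.
#' @param column_map Named character vector mapping the roles `sample`, `time`
#'   and `event` to the column names used in the file.
#' @return A data.frame of class `"clinical_table"` with columns `sample_id`,
#'   `time`, `event`, plus one column per covariate.
#' @export
read_clinical_table <- function(path,
                                column_map = c(sample = "sample", time = "time",
                                               event = "event")) {
  if (!file.exists(path)) stopf("cannot read clinical table: %s", path)
  for (role in c("sample", "time", "event"))
    if (!role %in% names(column_map)) stopf("column_map is missing the '%s' role", role)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (cn in column_map[c("sample", "time", "event")])
    if (!cn %in% colnames(df)) stopf("missing mandatory column '%s' in %s", cn, path)
  out <- data.frame(sample_id = as.character(df[[column_map[["sample"]]]]),
                    time = suppressWarnings(as.numeric(df[[column_map[["time"]]]])),
                    stringsAsFactors = FALSE)
  ev_raw <- tolower(trimws(as.character(df[[column_map[["event"]]]])))
  ev <- unname(.event_synonyms[ev_raw])
  unknown <- !is.na(ev_raw) & ev_raw != "" & ev_raw != "na" & is.na(ev)
  if (any(unknown))
    stopf("unmappable event value(s): %s",
          paste(unique(ev_raw[unknown]), collapse = ", "))
  out$event <- ev
  covar <- setdiff(colnames(df), column_map[c("sample", "time", "event")])
  for (cn in covar) out[[cn]] <- df[[cn]]
  if (anyDuplicated(out$sample_id)) stopf("duplicate sample identifier in %s", path)
  if (any(out$time < 0, na.rm = TRUE)) stopf("negative survival time in %s", path)
  incomplete <- is.na(out$time) | is.na(out$event)
  if (any(incomplete)) {
    warnf("excluded %d sample(s) with missing follow-up time or vital status",
          sum(incomplete))
    out <- out[!incomplete, , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Write a clinical table as TSV
#' @param clinical A `clinical_table` (or compatible data.frame).
#' @param path Output path.
#' @export
write_clinical_table <- function(clinical, path) {
  df <- as.data.frame(clinical)
  names(df)[names(df) == "sample_id"] <- "sample"
  df$event <- ifelse(df$event, "deceased", "living")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-site prediction table
#'
#' Tab-separated with columns `mir`, `gene`, `tool` (one row per prediction).
#' Duplicate (mir, gene, tool) triples are collapsed. When `tools` is given,
#' rows naming a tool outside that vocabulary are an error.
#'
#' @param path Path to the TSV file.
#' @param tools Optional character vector: the allowed tool vocabulary, e.g.
#'   [mirecords_tools()].
#' @return A data.frame of class `"binding_predictions"` with columns
#'   `mir_id`, `gene_id`, `tool`.
#' @export
read_prediction_table <- function(path, tools = NULL) {
  if (!file.exists(path)) stopf("cannot read prediction table: %s", path)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) {
    df <- data.frame(mir_id = character(), gene_id = character(),
                     tool = character(), stringsAsFactors = FALSE)
    class(df) <- c("binding_predictions", "data.frame")
    return(df)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (cn in c("mir", "gene", "tool"))
    if (!cn %in% colnames(df)) stopf("missing column '%s' in %s", cn, path)
  out <- data.frame(mir_id = as.character(df$mir),
                    gene_id = as.character(df$gene),
                    tool = as.character(df$tool), stringsAsFactors = FALSE)
  if (!is.null(tools)) {
    bad <- setdiff(unique(out$tool), tools)
    if (length(bad)) stopf("unknown prediction tool(s): %s", paste(bad, collapse = ", "))
  }
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("binding_predictions", "data.frame")
  out
}

#' The 11 prediction programs aggregated by the miRecords resource
#' @return Character vector of tool names.
#' @export
mirecords_tools <- function() {
  c("DIANA-microT", "MicroInspector", "miRanda", "MirTarget2", "miTarget",
    "NBmiRTar", "PicTar", "PITA", "RNA22", "RNAhybrid", "TargetScan")
}

#' Align expression matrices and clinical table on their common samples
#'
#' Restricts all three inputs to the samples present in every one of them, in
#' lexicographic (C-locale) order so downstream seeded computations are
#' reproducible across platforms, and reports how many samples each input
#' lost. Aligning an already-aligned dataset is a no-op.
#'
#' @param gene_expr,mir_expr Numeric expression matrices (features x samples).
#' @param clinical A `clinical_table`.
#' @param min_group_size Minimum subgroup size the downstream screen will use;
#'   alignment fails unless at least `2 * min_group_size` common samples
#'   remain.
#' @return An object of class `"aligned_dataset"`: list with `gene_expr`,
#'   `mir_expr`, `clinical`, `sample_ids`, `dropped` (per-input counts).
#' @export
align_dataset <- function(gene_expr, mir_expr, clinical, min_group_size = 10) {
  common <- intersect(intersect(colnames(gene_expr), colnames(mir_expr)),
                      clinical$sample_id)
  common <- sort(common, method = "radix")
  if (length(common) < 2 * min_group_size)
    stopf("insufficient common samples: %d found, need at least %d",
          length(common), 2 * min_group_size)
  dropped <- c(gene = ncol(gene_expr) - length(common),
               mir = ncol(mir_expr) - length(common),
               clinical = nrow(clinical) - length(common))
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  structure(list(gene_expr = gene_expr[, common, drop = FALSE],
                 mir_expr = mir_expr[, common, drop = FALSE],
                 clinical = cl,
                 sample_ids = common,
                 dropped = dropped),
            class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Aligned miR/gene expression + survival dataset\n")
  cat(sprintf("  samples: %d (dropped: gene %d, mir %d, clinical %d)\n",
              length(x$sample_ids), x$dropped[["gene"]], x$dropped[["mir"]],
              x$dropped[["clinical"]]))
  cat(sprintf("  genes: %d, miRs: %d, observed deaths: %d\n",
              nrow(x$gene_expr), nrow(x$mir_expr), sum(x$clinical$event)))
  invisible(x)
}
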