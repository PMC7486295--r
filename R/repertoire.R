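#' Per-cell OR repertoire profile
#'
#' Counts, per cell, the active functional ORs (`or_count`, the column sum of
#' the functional-OR activation block) and the mean log2(TPM+1) over that
#' cell's active ORs (`mean_or_expression`, 0 for cells with none).
#' "Expressed OR" is defined by the activation call (`z > -3`), not by raw
#' TPM positivity, so per-cell counts and dataset-level OR positivity share
#' one definition.
#'
#' @param activation an `activation_matrix`
#' @param catalog a `gene_catalog`
#' @param expression optional `expression_matrix` (TPM or log2) aligned with
#'   the activation matrix, used for `mean_or_expression`
#' @return `data.frame` of class `repertoire_profile` with columns
#'   `cell_id`, `or_count`, `mean_or_expression`
#' @export
or_counts_per_cell <- function(activation, catalog, expression = NULL) {
  stopifnot(inherits(activation, "activation_matrix"),
            inherits(catalog, "gene_catalog"))
  or_f <- catalog$symbol[catalog$family == "OR" &
                           catalog$status == "functional"]
  rows <- intersect(rownames(activation), or_f)
  block <- activation[rows, , drop = FALSE]
  k <- colSums(block)
  mean_expr <- rep(0, ncol(block))
  if (!is.null(expression)) {
    stopifnot(inherits(expression, "expression_matrix"))
    if (!identical(colnames(expression$values), colnames(activation)))
      stop("expression and activation matrices disagree on cells")
    lg <- as_log2_tpm1(expression)$values
    lg <- lg[rows, , drop = FALSE]
    for (j in seq_along(k)) {
      act <- block[, j] == 1L
      if (any(act)) mean_expr[j] <- mean(lg[act, j])
    }
  }
  out <- data.frame(cell_id = colnames(activation),
                    or_count = as.integer(k),
                    mean_or_expression = mean_expr,
                    stringsAsFactors = FALSE)
  class(out) <- c("repertoire_profile", "data.frame")
  out
}

#' OR co-expression distribution
#'
#' Distribution of per-cell expressed-OR counts, plus the fraction of cells
#' obeying the "one or none" rule (at most one expressed OR), the pattern
#' mature olfactory sensory neurons follow.
#'
#' @param profile a `repertoire_profile`
#' @return list with `table` (`data.frame`: `or_count`, `n_cells`,
#'   `percent`) and `one_or_none_fraction`
#' @export
coexpression_distribution <- function(profile) {
  stopifnot(inherits(profile, "repertoire_profile"))
  n <- nrow(profile)
  if (n == 0) stop("empty repertoire profile")
  tab <- table(profile$or_count)
  out <- data.frame(or_count = as.integer(names(tab)),
                    n_cells = as.integer(tab),
                    percent = 100 * as.integer(tab) / n,
                    row.names = NULL)
  list(table = out,
       one_or_none_fraction = mean(profile$or_count <= 1))
}

#' Tumor-type specificity of OR activation
#'
#' Given gene-level activation across several datasets (tumor types), lists
#' for every OR the datasets where it is active, its breadth, and whether it
#' is exclusive (one dataset) or broad. ORs active nowhere are omitted.
#' Dataset-level detection uses the gene-level median-z rule
#' ([call_active_genes()]); precomputed logical vectors are also accepted.
#'
#' @param z_by_dataset named list, one entry per dataset: either a
#'   `zscore_matrix` or a named logical vector of gene activity
#' @param catalog a `gene_catalog`
#' @return `data.frame` of class `specificity_table` with columns
#'   `or_symbol`, `breadth`, `class`, `datasets`
#' @export
tumor_specificity <- function(z_by_dataset, catalog) {
  stopifnot(is.list(z_by_dataset), length(z_by_dataset) >= 1,
            !is.null(names(z_by_dataset)),
            inherits(catalog, "gene_catalog"))
  or_f <- catalog$symbol[catalog$family == "OR" &
                           catalog$status == "functional"]
  active <- lapply(z_by_dataset, function(zz) {
    act <- if (inherits(zz, "zscore_matrix")) call_active_genes(zz) else zz
    names(act)[act]
  })
  hits <- lapply(or_f, function(g)
    names(active)[vapply(active, function(a) g %in% a, TRUE)])
  keep <- lengths(hits) >= 1
  out <- data.frame(or_symbol = or_f[keep],
                    breadth = lengths(hits)[keep],
                    class = ifelse(lengths(hits)[keep] == 1,
                                   "exclusive", "broad"),
                    datasets = vapply(hits[keep], paste, "", collapse = ";"),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("specificity_table", "data.frame")
  out
}

#' Correlation between per-cell OR count and OR expression level
#'
#' Tests whether cells expressing more ORs also express them more strongly.
#' Cells with zero expressed ORs are excluded (their mean expression is a
#' structural zero, not a measurement). The test is normality-gated, see
#' [gated_correlation()].
#'
#' @param profile a `repertoire_profile`
#' @return list with `r`, `p`, `test_used`, `n`
#' @export
count_expression_correlation <- function(profile) {
  stopifnot(inherits(profile, "repertoire_profile"))
  keep <- profile$or_count > 0
  if (sum(keep) < 3) stop("need >= 3 cells with at least one expressed OR")
  gated_correlation(profile$or_count[keep],
                    profile$mean_or_expression[keep])
}
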