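#' Expression matrix container
#'
#' A light container for a non-negative genes x samples abundance matrix with
#' a scale tag and optional per-sample metadata. The orientation contract is
#' fixed: rows are genes, columns are samples (cells or patients).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique non-empty dimnames. All entries must be finite and non-negative.
#' @param scale unit tag, one of `"TPM"` (transcripts per million) or
#'   `"LOG2_TPM1"` (log2(TPM+1)).
#' @param sample_meta optional `data.frame` with one row per sample (matched
#'   by order or by a `sample_id` column). Conventional columns are
#'   `dataset`, `condition` (one of healthy, tumor-tissue, CTC, PDX,
#'   cell-line, bulk), `subtype` and `cluster`; all are optional.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values`, `scale` and `sample_meta`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 2, 5), 2, 2,
#'             dimnames = list(c("OR1A1", "ACTB"), c("c1", "c2")))
#' em <- expression_matrix(m, scale = "TPM")
#' dim(em)
expression_matrix <- function(values, scale = c("TPM", "LOG2_TPM1"),
                              sample_meta = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in matrix rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in matrix columns")
  if (any(!is.finite(values)))
    stop("non-finite entries in expression matrix")
  if (any(values < 0))
    stop("negative entries in expression matrix; abundances must be >= 0")
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != ncol(values))
      stop("sample_meta has ", nrow(sample_meta), " rows but matrix has ",
           ncol(values), " samples")
    rownames(sample_meta) <- colnames(values)
  }
  structure(list(values = values, scale = scale, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
dimnames.expression_matrix <- function(x) dimnames(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$scale, "]\n", sep = "")
  invisible(x)
}

#' Gene and sample accessors
#' @param x an `expression_matrix`
#' @return character vector of identifiers
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Convert an expression matrix to the log2(TPM+1) scale
#'
#' Idempotent: a matrix already on the `LOG2_TPM1` scale is returned as is.
#'
#' @param x an `expression_matrix`
#' @return an `expression_matrix` with scale `LOG2_TPM1`
#' @export
as_log2_tpm1 <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (x$scale == "LOG2_TPM1") return(x)
  expression_matrix(log2(x$values + 1), scale = "LOG2_TPM1",
                    sample_meta = x$sample_meta)
}

#' Rescale every sample to a fixed total (TPM renormalization)
#'
#' @param values non-negative matrix, genes x samples
#' @param total column target sum, 10^6 for TPM
#' @return matrix whose columns each sum to `total`
#' @keywords internal
tpm_normalize <- function(values, total = 1e6) {
  cs <- colSums(values)
  if (any(cs <= 0)) stop("cannot TPM-normalize a sample with zero total")
  sweep(values, 2, cs / total, "/")
}

#' Subset an expression matrix by sample
#' @param x an `expression_matrix`
#' @param samples logical, integer or character selector on columns
#' @return an `expression_matrix`
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- x$values[, samples, drop = FALSE]
  meta <- if (is.null(x$sample_meta)) NULL else
    x$sample_meta[colnames(v), , drop = FALSE]
  expression_matrix(v, scale = x$scale, sample_meta = meta)
}
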