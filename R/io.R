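#' Read an expression matrix from disk
#'
#' Supported formats: dense TSV/CSV with a header row of sample ids and the
#' first column holding gene symbols, and Matrix Market coordinate (`mtx`)
#' with companion `genes.tsv` / `barcodes.tsv` files (one identifier per
#' line) next to the matrix file. MTX values are read as real abundances
#' (TPM), not integer counts; absent triplets are zeros.
#'
#' Duplicate gene symbols are a hard error unless `dedupe = "sum"`, which
#' aggregates duplicate rows by summation. Silent aggregation is not the
#' default because it corrupts per-cell receptor counts.
#'
#' @param path file path (for `mtx`, the `.mtx` file)
#' @param format `"tsv"`, `"csv"` or `"mtx"`
#' @param scale scale tag of the stored values, see [expression_matrix()]
#' @param dedupe `"error"` (default) or `"sum"`
#' @return an `expression_matrix`
#' @export
load_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            scale = "TPM", dedupe = c("error", "sum")) {
  format <- match.arg(format)
  dedupe <- match.arg(dedupe)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "mtx") {
    dir <- dirname(path)
    gene_file <- file.path(dir, "genes.tsv")
    bc_file <- file.path(dir, "barcodes.tsv")
    if (!file.exists(gene_file) || !file.exists(bc_file))
      stop("mtx companions genes.tsv/barcodes.tsv not found in ", dir)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    bcs <- readLines(bc_file)
    if (nrow(m) != length(genes) || ncol(m) != length(bcs))
      stop("dimension mismatch: matrix is ", nrow(m), "x", ncol(m),
           " but id files list ", length(genes), " genes / ",
           length(bcs), " barcodes")
    dimnames(m) <- list(genes, bcs)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("expected a gene column plus >=1 sample column")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
  }
  if (any(!is.finite(m))) stop("non-finite value in ", path)
  if (any(m < 0)) stop("negative value in ", path, "; abundances must be >= 0")
  if (anyDuplicated(rownames(m))) {
    if (dedupe == "error")
      stop("duplicate gene symbols in ", path,
           " (set dedupe = \"sum\" to aggregate)")
    m <- rowsum(m, group = rownames(m), reorder = FALSE)
  }
  expression_matrix(m, scale = scale)
}

#' Write an expression matrix to disk
#'
#' Inverse of [load_expression()]: `load_expression(write_matrix(m))`
#' reproduces `m` up to representation precision.
#'
#' @param matrix an `expression_matrix` with at least one gene and one sample
#' @param path destination path (for `mtx`, the `.mtx` file; companions are
#'   written alongside)
#' @param format `"tsv"`, `"csv"` or `"mtx"`
#' @return `path`, invisibly
#' @export
write_matrix <- function(matrix, path, format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "expression_matrix"))
  v <- matrix$values
  if (nrow(v) == 0 || ncol(v) == 0)
    stop("refusing to write an empty matrix (", nrow(v), " genes x ",
         ncol(v), " samples)")
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(v), file.path(dir, "genes.tsv"))
    writeLines(colnames(v), file.path(dir, "barcodes.tsv"))
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- data.frame(gene = rownames(v), v, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a chemoreceptor catalog TSV
#'
#' Expected columns: `symbol`, `family`, `or_class`, `chromosome`, `status`
#' (`or_class` optional). Vocabulary violations and duplicate symbols are
#' errors, see [gene_catalog()].
#'
#' @param path TSV file path
#' @return a `gene_catalog`
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  needed <- c("symbol", "family", "chromosome", "status")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  gene_catalog(df$symbol, df$family, df$chromosome, df$status,
               or_class = if ("or_class" %in% names(df)) df$or_class
                          else NA_character_)
}

#' Write a chemoreceptor catalog TSV
#' @param catalog a `gene_catalog`
#' @param path destination TSV path
#' @return `path`, invisibly
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a survival table TSV
#'
#' Columns: `patient_id`, `time` (>= 0), `event` (0 = censored, 1 = event)
#' and optional `group`.
#'
#' @param path TSV file path
#' @return a `data.frame` of class `survival_table`
#' @export
load_survival <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  survival_table(df$patient_id, df$time, df$event,
                 group = if ("group" %in% names(df)) df$group else NULL)
}

#' Survival table constructor
#' @param patient_id unique patient identifiers
#' @param time non-negative follow-up times
#' @param event 0 (censored) or 1 (event)
#' @param group optional categorical group label
#' @return a `data.frame` of class `survival_table`
#' @export
survival_table <- function(patient_id, time, event, group = NULL) {
  patient_id <- as.character(patient_id)
  if (anyDuplicated(patient_id)) stop("duplicate patient ids")
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time < 0))
    stop("survival times must be finite and >= 0")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be 0 or 1")
  out <- data.frame(patient_id = patient_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  out$group <- if (is.null(group)) NA_character_ else as.character(group)
  class(out) <- c("survival_table", "data.frame")
  out
}

#' Read gene sets from a GMT file
#'
#' One set per line: set name, description, then tab-separated member gene
#' symbols.
#'
#' @param path GMT file path
#' @return named list of character vectors
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path destination path
#' @param description description field per set (recycled)
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
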