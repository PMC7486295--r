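#' Chemoreceptor gene catalog
#'
#' Annotation table for the human chemosensory receptor repertoire: odorant
#' receptors (OR, ~400 functional genes plus ~600 pseudogenes), trace
#' amine-associated receptors (TAAR), vomeronasal receptors (V1R/V2R) and
#' taste receptors (T1R/T2R). Gene identity is by symbol string,
#' case-sensitive; no alias resolution is attempted.
#'
#' @param symbol character, unique gene symbols
#' @param family character, each one of `OR`, `TAAR`, `V1R`, `V2R`, `T1R`,
#'   `T2R`
#' @param chromosome character, non-empty chromosome names
#' @param status character, each one of `functional`, `pseudogene`
#' @param or_class optional OR class (`ClassI`/`ClassII`), `NA` allowed
#' @return a `data.frame` of class `gene_catalog` with columns `symbol`,
#'   `family`, `or_class`, `chromosome`, `status`
#' @export
gene_catalog <- function(symbol, family, chromosome, status,
                         or_class = NA_character_) {
  fam_vocab <- c("OR", "TAAR", "V1R", "V2R", "T1R", "T2R")
  status_vocab <- c("functional", "pseudogene")
  symbol <- as.character(symbol)
  family <- as.character(family)
  chromosome <- as.character(chromosome)
  status <- as.character(status)
  if (anyDuplicated(symbol))
    stop("duplicate symbols in gene catalog: ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  bad_fam <- setdiff(unique(family), fam_vocab)
  if (length(bad_fam))
    stop("unknown chemoreceptor family token(s): ",
         paste(bad_fam, collapse = ", "))
  bad_status <- setdiff(unique(status), status_vocab)
  if (length(bad_status))
    stop("unknown status token(s): ", paste(bad_status, collapse = ", "))
  if (any(is.na(chromosome) | !nzchar(chromosome)))
    stop("empty chromosome names in catalog")
  out <- data.frame(symbol = symbol, family = family,
                    or_class = rep_len(as.character(or_class), length(symbol)),
                    chromosome = chromosome, status = status,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_catalog", "data.frame")
  out
}

#' Restrict an expression matrix to catalog genes
#'
#' Keeps the matrix rows whose symbols belong to the catalog entries matching
#' the requested families and functional status, preserving the matrix's
#' original row order. Catalog genes absent from the matrix are reported via
#' the `"absent_genes"` attribute, not treated as errors; an empty
#' intersection yields a 0-row matrix with a warning.
#'
#' @param matrix an `expression_matrix`
#' @param catalog a `gene_catalog`
#' @param families families to keep (non-empty subset of the family vocabulary)
#' @param status statuses to keep, default both
#' @return an `expression_matrix` restricted to the selected genes, with
#'   attribute `absent_genes` listing selected catalog genes not in the matrix
#' @export
subset_genes <- function(matrix, catalog, families,
                         status = c("functional", "pseudogene")) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(catalog, "gene_catalog"))
  if (length(families) == 0) stop("empty family selection")
  wanted <- catalog$symbol[catalog$family %in% families &
                             catalog$status %in% status]
  keep <- rownames(matrix$values) %in% wanted
  if (!any(keep))
    warning("no matrix genes match the requested families/status; ",
            "returning a 0-row matrix")
  v <- matrix$values[keep, , drop = FALSE]
  out <- structure(list(values = v, scale = matrix$scale,
                        sample_meta = matrix$sample_meta),
                   class = "expression_matrix")
  attr(out, "absent_genes") <- setdiff(wanted, rownames(matrix$values))
  out
}

#' Minimum-cell-count dataset gate
#'
#' Single-cell datasets below a minimum number of cells are too small for
#' stable per-cell activation fits; the gate is inclusive (a dataset with
#' exactly `min_cells` samples passes).
#'
#' @param matrix an `expression_matrix`
#' @param min_cells inclusive lower bound on sample count, default 60
#' @return a list of class `dataset_report` with `pass`, `n_cells`,
#'   `min_cells`, `n_genes`
#' @export
validate_dataset <- function(matrix, min_cells = 60L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  n <- ncol(matrix$values)
  structure(list(pass = n >= min_cells, n_cells = n,
                 min_cells = as.integer(min_cells),
                 n_genes = nrow(matrix$values)),
            class = "dataset_report")
}

#' @export
print.dataset_report <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL", ": ", x$n_cells, " cells (minimum ",
      x$min_cells, "), ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Per-chromosome detection summary
#'
#' Tabulates, per chromosome in the catalog, how many catalog genes exist and
#' how many of them were detected, the tabular counterpart of a chromosome
#' ideogram of detected receptor loci.
#'
#' @param catalog a `gene_catalog`
#' @param detected_genes character vector of detected gene symbols; symbols
#'   not in the catalog are reported with a warning and ignored
#' @return `data.frame` with columns `chromosome`, `n_catalog`, `n_detected`,
#'   `fraction_detected`
#' @export
chromosome_summary <- function(catalog, detected_genes) {
  stopifnot(inherits(catalog, "gene_catalog"))
  detected_genes <- unique(as.character(detected_genes))
  unknown <- setdiff(detected_genes, catalog$symbol)
  if (length(unknown))
    warning(length(unknown), " detected symbol(s) absent from catalog, ",
            "ignored: ", paste(head(unknown, 5), collapse = ", "))
  detected <- intersect(detected_genes, catalog$symbol)
  chroms <- unique(catalog$chromosome)
  n_cat <- vapply(chroms, function(ch) sum(catalog$chromosome == ch), 0L)
  n_det <- vapply(chroms, function(ch)
    sum(catalog$symbol[catalog$chromosome == ch] %in% detected), 0L)
  data.frame(chromosome = chroms, n_catalog = as.integer(n_cat),
             n_detected = as.integer(n_det),
             fraction_detected = ifelse(n_cat > 0, n_det / n_cat, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}
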