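#' Single-sample gene-set enrichment scores (GSVA-style)
#'
#' Non-parametric per-sample gene-set scoring by a rank-weighted
#' Kolmogorov-Smirnov random walk, in the style of Gene Set Variation
#' Analysis. Stages: (1) per gene i, a Gaussian-kernel cumulative density
#' estimate of each sample's expression relative to the gene's own
#' distribution, `F[i, j] = mean over samples j' of
#' pnorm((x[i,j] - x[i,j']) / (s_i / 4))` with `s_i` the gene's sd across
#' samples (floored at 1e-8 for constant genes); (2) per sample, genes are
#' ranked by `F` in decreasing order (ties by row index) and the ranks are
#' centered symmetrically about zero; (3) for each gene set a random walk
#' down the ranked list accumulates `|centered rank|^tau` (normalized) at
#' member genes and a uniform penalty `1/(n_genes - set size)` at
#' non-members; (4) the enrichment score in `max_diff` mode is the walk's
#' largest positive deviation plus its most negative deviation.
#'
#' @param matrix an `expression_matrix`; TPM input is log2(TPM+1) transformed
#'   first, `LOG2_TPM1` input is used as is
#' @param sets named list of gene-symbol vectors; sets with no gene in the
#'   matrix are dropped with a warning
#' @param tau rank-weight exponent, default 1
#' @param es_mode enrichment-score summary; `"max_diff"` (the only mode)
#' @return matrix (sets x samples) of class `enrichment_scores` with
#'   attributes `tau`, `es_mode`, `kernel`
#' @export
gsva_scores <- function(matrix, sets, tau = 1, es_mode = "max_diff") {
  stopifnot(inherits(matrix, "expression_matrix"), is.list(sets),
            !is.null(names(sets)))
  es_mode <- match.arg(es_mode, "max_diff")
  x <- as_log2_tpm1(matrix)$values
  n_genes <- nrow(x)
  n_samp <- ncol(x)
  if (n_samp < 2) stop("need >= 2 samples for kernel CDF estimation")
  idx_sets <- lapply(sets, function(g) which(rownames(x) %in% g))
  empty <- lengths(idx_sets) == 0
  if (any(empty)) {
    warning("dropping gene set(s) with no genes in the matrix: ",
            paste(names(sets)[empty], collapse = ", "))
    idx_sets <- idx_sets[!empty]
  }
  if (length(idx_sets) == 0) stop("no gene set overlaps the matrix")
  full_sets <- lengths(idx_sets) >= n_genes
  if (any(full_sets))
    stop("gene set(s) covering every matrix gene leave no non-members: ",
         paste(names(idx_sets)[full_sets], collapse = ", "))

  # (1) per-gene Gaussian kernel CDF of each sample value
  kcdf <- base::matrix(0, n_genes, n_samp, dimnames = dimnames(x))
  for (i in seq_len(n_genes)) {
    bw <- max(sd(x[i, ]) / 4, 1e-8)
    kcdf[i, ] <- colMeans(pnorm(outer(x[i, ], x[i, ], FUN = function(a, b)
      (b - a) / bw)))
  }

  # (2) decreasing-F ranks, symmetrically centered about zero
  out <- base::matrix(NA_real_, length(idx_sets), n_samp,
                      dimnames = list(names(idx_sets), colnames(x)))
  for (j in seq_len(n_samp)) {
    ord <- order(-kcdf[, j], seq_len(n_genes))   # rank 1 = largest F
    centered <- (n_genes + 1) / 2 - seq_len(n_genes)  # +max at rank 1
    w <- abs(centered)^tau
    member_at_pos <- base::matrix(FALSE, n_genes, length(idx_sets))
    pos_of_gene <- integer(n_genes)
    pos_of_gene[ord] <- seq_len(n_genes)
    for (s in seq_along(idx_sets))
      member_at_pos[pos_of_gene[idx_sets[[s]]], s] <- TRUE
    # (3)-(4) weighted KS walk per set
    for (s in seq_along(idx_sets)) {
      mem <- member_at_pos[, s]
      m <- sum(mem)
      step <- ifelse(mem, w / sum(w[mem]), -1 / (n_genes - m))
      walk <- cumsum(step)
      out[s, j] <- max(c(0, walk)) + min(c(0, walk))
    }
  }
  attr(out, "tau") <- tau
  attr(out, "es_mode") <- es_mode
  attr(out, "kernel") <- "gaussian"
  class(out) <- c("enrichment_scores", class(out))
  out
}

#' Correlate OR expression with pathway enrichment scores
#'
#' One normality-gated correlation per (OR, signature) pair across cells;
#' pairs where either variable has zero variance are flagged and skipped.
#'
#' @param scores an `enrichment_scores` matrix (signatures x cells)
#' @param or_expression matrix of per-cell OR expression (ORs x cells,
#'   log2(TPM+1)); column names must match `scores`
#' @return `data.frame` with columns `or_symbol`, `signature`, `r`, `p`,
#'   `test_used`, `direction` (sign of r), `flag`
#' @export
correlate_or_pathways <- function(scores, or_expression) {
  stopifnot(inherits(scores, "enrichment_scores"))
  or_expression <- as.matrix(or_expression)
  if (!identical(colnames(scores), colnames(or_expression)))
    stop("scores and OR expression disagree on sample ids")
  rows <- list()
  for (or in rownames(or_expression)) {
    for (sig in rownames(scores)) {
      xo <- or_expression[or, ]
      xs <- scores[sig, ]
      if (sd(xo) == 0 || sd(xs) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          or_symbol = or, signature = sig, r = NA_real_, p = NA_real_,
          test_used = NA_character_, direction = NA_real_,
          flag = "zero_variance", stringsAsFactors = FALSE)
        next
      }
      ct <- gated_correlation(xo, xs)
      rows[[length(rows) + 1L]] <- data.frame(
        or_symbol = or, signature = sig, r = ct$r, p = ct$p,
        test_used = ct$test_used, direction = sign(ct$r), flag = "ok",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
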