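#' Cosine similarity of two vectors
#'
#' `cos(A, B) = sum(A*B) / (sqrt(sum(A^2)) * sqrt(sum(B^2)))`; in `[0, 1]`
#' for non-negative vectors. Zero-norm vectors are an error (the similarity
#' is undefined).
#'
#' @param a,b numeric vectors of equal length
#' @return cosine similarity
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Build cluster-level OR signatures from single cells
#'
#' Cells are clustered hierarchically on their binary OR activation profiles
#' (Jaccard distance, average linkage by default; Euclidean distance on
#' sparse presence/absence profiles would be dominated by shared absence of
#' rarely expressed receptors). Each signature is the per-gene mean
#' log2(TPM+1) of its member cells, annotated with the member count and mean
#' per-cell OR count, so distinct signatures represent subpopulations with
#' distinct numbers of expressed ORs.
#'
#' @param or_log_matrix `expression_matrix` restricted to functional OR
#'   genes (TPM input is log2-transformed internally)
#' @param activation an `activation_matrix` over the same genes and cells
#' @param n_clusters integer `k`, or `"auto"` to pick `k` in `[2, 8]` by
#'   maximum mean silhouette width on the Jaccard distances
#' @param linkage hclust agglomeration method, default `"ward.D2"` (average
#'   linkage chains badly on sparse binary receptor profiles, where most
#'   pairwise Jaccard distances sit at exactly 1)
#' @return list of class `or_signatures`: `signatures` (genes x k matrix of
#'   mean log2(TPM+1)), `meta` (`data.frame`: `cluster`, `n_cells`,
#'   `mean_or_count`), `cell_cluster` (named integer)
#' @export
build_or_signatures <- function(or_log_matrix, activation,
                                n_clusters = "auto", linkage = "ward.D2") {
  stopifnot(inherits(or_log_matrix, "expression_matrix"),
            inherits(activation, "activation_matrix"))
  if (!identical(dimnames(or_log_matrix$values), dimnames(activation)))
    stop("expression and activation matrices must share genes and cells")
  lg <- as_log2_tpm1(or_log_matrix)$values
  bin <- t(activation == 1L)                    # cells x ORs
  n <- nrow(bin)
  d <- dist(bin, method = "binary")             # Jaccard distance
  d[is.nan(d)] <- 0                             # two empty OR sets coincide
  degenerate <- all(d == 0)
  if (degenerate) {
    if (!identical(n_clusters, "auto") && n_clusters > 1)
      stop("all cells share one binary OR profile; cannot form ",
           n_clusters, " clusters")
    cl <- setNames(rep(1L, n), rownames(bin))
  } else {
    hc <- hclust(d, method = linkage)
    if (identical(n_clusters, "auto")) {
      ks <- 2:min(8L, n - 1L)
      sil <- vapply(ks, function(k)
        mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"]), 0)
      n_clusters <- ks[which.max(sil)]
    }
    if (n_clusters > n) stop("more clusters requested than cells")
    cl <- setNames(cutree(hc, n_clusters), rownames(bin))
  }
  ids <- sort(unique(cl))
  sig <- vapply(ids, function(k)
    rowMeans(lg[, cl == k, drop = FALSE]), numeric(nrow(lg)))
  colnames(sig) <- paste0("signature", ids)
  rownames(sig) <- rownames(lg)
  k_per_cell <- colSums(activation)
  meta <- data.frame(cluster = ids,
                     n_cells = as.integer(table(cl)[as.character(ids)]),
                     mean_or_count = vapply(ids, function(k)
                       mean(k_per_cell[cl == k]), 0),
                     row.names = NULL)
  structure(list(signatures = sig, meta = meta, cell_cluster = cl),
            class = "or_signatures")
}

#' Project OR signatures onto bulk profiles
#'
#' Restricts the bulk matrix to the signatures' OR genes, log2(TPM+1)
#' transforms it, and fills a patients x signatures matrix of cosine
#' similarities. OR genes missing from the bulk matrix are treated as zeros
#' with a warning; patients whose restricted OR vector is all zero are
#' flagged (`NA` row) and excluded from downstream stratification.
#'
#' @param bulk a TPM `expression_matrix` (genes x patients)
#' @param signatures an `or_signatures` object (or a genes x k matrix)
#' @return matrix (patients x signatures) of class `similarity_matrix` with
#'   attributes `n_shared_genes` and `flagged` (all-zero patients)
#' @export
project_signatures <- function(bulk, signatures) {
  stopifnot(inherits(bulk, "expression_matrix"))
  sig <- if (inherits(signatures, "or_signatures")) signatures$signatures
         else as.matrix(signatures)
  zero_sig <- colSums(sig^2) == 0
  if (all(zero_sig)) stop("every signature is a zero vector")
  if (any(zero_sig)) {
    warning(sum(zero_sig), " zero signature(s) dropped from projection: ",
            paste(colnames(sig)[zero_sig], collapse = ", "))
    sig <- sig[, !zero_sig, drop = FALSE]
  }
  genes <- rownames(sig)
  shared <- intersect(genes, rownames(bulk$values))
  if (length(shared) == 0)
    stop("no OR genes shared between bulk matrix and signatures")
  if (length(shared) < length(genes))
    warning(length(genes) - length(shared),
            " signature OR gene(s) absent from bulk, treated as zero")
  if (length(shared) < 10)
    warning("only ", length(shared), " shared OR genes; projection unstable")
  b <- base::matrix(0, length(genes), ncol(bulk$values),
                    dimnames = list(genes, colnames(bulk$values)))
  b[shared, ] <- as_log2_tpm1(bulk)$values[shared, , drop = FALSE]
  out <- base::matrix(NA_real_, ncol(b), ncol(sig),
                      dimnames = list(colnames(b), colnames(sig)))
  zero <- colSums(b) == 0
  for (p in which(!zero))
    for (s in seq_len(ncol(sig)))
      out[p, s] <- cosine_similarity(sig[, s], b[, p])
  if (any(zero))
    warning(sum(zero), " patient(s) with all-zero OR vectors flagged")
  attr(out, "n_shared_genes") <- length(shared)
  attr(out, "flagged") <- colnames(b)[zero]
  class(out) <- c("similarity_matrix", class(out))
  out
}

#' Stratify patients from a similarity matrix
#'
#' Hierarchical clustering (Euclidean distance, Ward linkage) of the
#' patients' similarity-row vectors; `"auto"` picks the number of groups in
#' `[2, 6]` by maximum mean silhouette width. Flagged patients (NA rows)
#' keep an `NA` group.
#'
#' Two refinements clean up the raw dendrogram cut. With `center = TRUE`
#' (default) each patient's row is centered at its mean before clustering:
#' the similarities of one patient to all signatures share a common level
#' (driven by that patient's overall OR content), and the grouping signal is
#' the relative affinity pattern. With `refine = TRUE` (default) patients
#' are iteratively reassigned to the nearest group centroid until
#' convergence, the usual fix for boundary patients that a single dendrogram
#' cut places with the wrong branch; the procedure stays deterministic.
#'
#' @param sim a `similarity_matrix` from [project_signatures()]
#' @param n_groups integer, or `"auto"`
#' @param center center each similarity row at its mean before clustering
#' @param refine nearest-centroid reassignment after the cut
#' @return named group labels (`group1`, `group2`, ...; `NA` for flagged
#'   patients)
#' @export
stratify_patients <- function(sim, n_groups = "auto", center = TRUE,
                              refine = TRUE) {
  stopifnot(inherits(sim, "similarity_matrix"))
  valid <- rowSums(is.na(sim)) == 0
  m <- sim[valid, , drop = FALSE]
  if (center) m <- m - rowMeans(m)
  n <- nrow(m)
  if (identical(n_groups, "auto")) {
    if (n < 3) stop("need >= 3 valid patients for automatic group selection")
  } else if (n_groups > n) stop("more groups requested than valid patients")
  labels <- rep(NA_character_, nrow(sim))
  names(labels) <- rownames(sim)
  if (!identical(n_groups, "auto") && n_groups == 1) {
    labels[valid] <- "group1"
    return(labels)
  }
  d <- dist(m)
  hc <- hclust(d, method = "ward.D2")
  if (identical(n_groups, "auto")) {
    ks <- 2:min(6L, n - 1L)
    sil <- vapply(ks, function(k)
      mean(cluster::silhouette(cutree(hc, k), d)[, "sil_width"]), 0)
    n_groups <- ks[which.max(sil)]
  }
  g <- unname(cutree(hc, n_groups))
  if (refine && n_groups > 1) {
    for (it in seq_len(50)) {
      cent <- apply(m, 2, function(col) tapply(col, g, mean))
      dd <- as.matrix(dist(rbind(cent, m)))[-seq_len(nrow(cent)),
                                            seq_len(nrow(cent)),
                                            drop = FALSE]
      g2 <- as.integer(rownames(cent))[max.col(-dd, ties.method = "first")]
      if (identical(g2, g)) break
      g <- g2
    }
  }
  labels[valid] <- paste0("group", g)
  labels
}
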