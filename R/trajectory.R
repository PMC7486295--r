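#' Embed cells by PCA and cluster a mutual-kNN graph
#'
#' Per-gene standardization of log2(TPM+1) (zero-variance genes dropped,
#' standardized values clipped at `scale_max`, the usual guard against
#' zero-inflated genes dominating the distances), PCA to `n_pcs`, a mutual
#' k-nearest-neighbour graph on the embedding (Euclidean, distance ties
#' broken by column index), and community detection by greedy modularity
#' maximization. Everything is deterministic given the input and seed. A
#' disconnected graph is allowed: components are clustered independently and
#' the result is flagged.
#'
#' Chemoreceptor genes can be excluded via `exclude_genes` so that the
#' embedding — and any pseudotime later correlated with per-cell OR counts —
#' is defined by the rest of the transcriptome rather than by the receptors
#' themselves.
#'
#' @param matrix an `expression_matrix` with more cells than `n_pcs`
#' @param n_pcs number of principal components, default 30
#' @param k_nn neighbourhood size, default 15
#' @param seed integer seed (kept for interface stability; the procedure is
#'   deterministic)
#' @param exclude_genes optional gene symbols to drop before embedding
#' @param scale_max clip bound on standardized values, default 10
#' @return list of class `cell_embedding` with `embedding` (cells x PCs),
#'   `clusters` (named integer), `n_components` and `knn` (the neighbour
#'   index matrix)
#' @export
embed_and_cluster <- function(matrix, n_pcs = 30L, k_nn = 15L, seed = 1L,
                              exclude_genes = NULL, scale_max = 10) {
  stopifnot(inherits(matrix, "expression_matrix"))
  x <- t(as_log2_tpm1(matrix)$values)          # cells x genes
  if (!is.null(exclude_genes))
    x <- x[, !(colnames(x) %in% exclude_genes), drop = FALSE]
  n <- nrow(x)
  if (n <= n_pcs) stop("need more cells than n_pcs")
  sds <- apply(x, 2, sd)
  keep <- sds > 0
  if (!any(keep))
    stop("every gene has zero variance; nothing to embed")
  x <- scale(x[, keep, drop = FALSE])
  x[x > scale_max] <- scale_max
  x[x < -scale_max] <- -scale_max
  set.seed(seed)
  n_pcs <- min(n_pcs, n - 1L, ncol(x))
  emb <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  rownames(emb) <- colnames(matrix$values)

  nn <- knn_indices(emb, k_nn)
  # mutual kNN: keep edge i-j only if each lists the other
  edges <- integer(0)
  for (i in seq_len(n)) {
    for (j in nn[i, ]) {
      if (i < j && i %in% nn[j, ]) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  # connectivity guard: a cell none of whose neighbours list it back would
  # be stranded; tie it to its single nearest neighbour
  deg0 <- which(igraph::degree(g) == 0)
  if (length(deg0))
    g <- igraph::add_edges(g, as.vector(rbind(deg0, nn[deg0, 1])))
  comp <- igraph::components(g)
  cl <- igraph::membership(igraph::cluster_fast_greedy(g))
  clusters <- setNames(as.integer(cl), rownames(emb))
  structure(list(embedding = emb, clusters = clusters,
                 n_components = comp$no, knn = nn),
            class = "cell_embedding")
}

#' k-nearest-neighbour indices with deterministic tie-breaking
#' @param emb numeric matrix (points x dims)
#' @param k neighbours per point (self excluded)
#' @return integer matrix (points x k)
#' @keywords internal
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  if (k >= n) stop("k_nn must be smaller than the number of cells")
  d2 <- as.matrix(dist(emb))^2
  diag(d2) <- Inf
  t(vapply(seq_len(n), function(i)
    order(d2[i, ], seq_len(n))[seq_len(k)], integer(k)))
}

#' Select the trajectory root from stemness scores
#'
#' The root cluster is the cluster with the highest mean stemness score
#' (rooting the differentiation trajectory where cells are collectively most
#' stem-like); exact ties go to the smallest cluster id with a warning. The root cell is the embedding medoid of the
#' root cluster (the member minimizing total Euclidean distance to the other
#' members).
#'
#' @param embed a `cell_embedding`
#' @param stemness named (or aligned) numeric per-cell stemness score
#' @return list with `root_cluster`, `root_cell`, `cluster_means`
#' @export
select_root <- function(embed, stemness) {
  stopifnot(inherits(embed, "cell_embedding"))
  cells <- rownames(embed$embedding)
  if (!is.null(names(stemness))) stemness <- stemness[cells]
  if (length(stemness) != length(cells) || any(!is.finite(stemness)))
    stop("stemness must provide one finite score per embedded cell")
  means <- tapply(stemness, embed$clusters, mean)
  top <- names(means)[means == max(means)]
  if (length(top) > 1) {
    warning("stemness tie between clusters ",
            paste(top, collapse = ", "), "; choosing the smallest id")
    top <- top[order(as.integer(top))][1]
  }
  members <- which(embed$clusters == as.integer(top))
  sub <- embed$embedding[members, , drop = FALSE]
  dd <- as.matrix(dist(sub))
  medoid <- members[which.min(rowSums(dd))]
  list(root_cluster = as.integer(top),
       root_cell = cells[medoid],
       cluster_means = means)
}

#' Geodesic pseudotime from a root cell
#'
#' Pseudotime is the Dijkstra shortest-path distance from the root cell on a
#' symmetrized (union) kNN graph over the embedding with Euclidean edge
#' weights, rescaled to `[0, 1]` by the largest finite distance. The union
#' graph (an edge exists if either endpoint lists the other as a neighbour)
#' is used rather than the mutual graph so the ordering reaches as many
#' cells as possible; cells still unreachable from the root get `NA` and are
#' flagged.
#'
#' @param embed a `cell_embedding` or a plain embedding matrix
#' @param root_cell root cell id (or index)
#' @param k_nn neighbourhood size, default 15
#' @return named numeric pseudotime in `[0, 1]` with attribute
#'   `unreachable` listing cells the root cannot reach
#' @export
compute_pseudotime <- function(embed, root_cell, k_nn = 15L) {
  emb <- if (inherits(embed, "cell_embedding")) embed$embedding else
    as.matrix(embed)
  n <- nrow(emb)
  cells <- rownames(emb)
  if (is.null(cells)) cells <- as.character(seq_len(n))
  root <- if (is.character(root_cell)) match(root_cell, cells) else
    as.integer(root_cell)
  if (is.na(root) || root < 1 || root > n) stop("unknown root cell")
  nn <- knn_indices(emb, k_nn)
  from <- rep(seq_len(n), each = k_nn)
  to <- as.vector(t(nn))
  w <- sqrt(rowSums((emb[from, , drop = FALSE] -
                       emb[to, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = "min")
  d <- as.numeric(igraph::distances(g, v = root, weights = igraph::E(g)$weight))
  unreachable <- cells[!is.finite(d)]
  d[!is.finite(d)] <- NA_real_
  mx <- max(d, na.rm = TRUE)
  pt <- if (mx > 0) d / mx else d
  names(pt) <- cells
  attr(pt, "unreachable") <- unreachable
  pt
}

#' Pseudotime correlation table
#'
#' Normality-gated correlations of pseudotime against stemness, per-cell OR
#' count and mean OR expression, plus stemness against OR count. Cells with
#' undefined pseudotime are dropped; rows with a zero-variance variable are
#' flagged rather than computed.
#'
#' @param pseudotime named numeric from [compute_pseudotime()]
#' @param stemness per-cell stemness scores aligned with `pseudotime`
#' @param profile a `repertoire_profile` for the same cells
#' @return `data.frame` with columns `pair`, `r`, `p`, `test_used`, `n`,
#'   `flag`
#' @export
pseudotime_correlations <- function(pseudotime, stemness, profile) {
  stopifnot(inherits(profile, "repertoire_profile"))
  cells <- names(pseudotime)
  prof <- profile[match(cells, profile$cell_id), ]
  if (!is.null(names(stemness))) stemness <- stemness[cells]
  ok <- is.finite(pseudotime)
  if (sum(ok) < 10) stop("need >= 10 cells with defined pseudotime")
  vars <- list(pseudotime = as.numeric(pseudotime)[ok],
               stemness = as.numeric(stemness)[ok],
               or_count = prof$or_count[ok],
               mean_or_expression = prof$mean_or_expression[ok])
  pairs <- list(c("pseudotime", "stemness"),
                c("pseudotime", "or_count"),
                c("pseudotime", "mean_or_expression"),
                c("stemness", "or_count"))
  rows <- lapply(pairs, function(pr) {
    a <- vars[[pr[1]]]; b <- vars[[pr[2]]]
    if (sd(a) == 0 || sd(b) == 0)
      return(data.frame(pair = paste(pr, collapse = " vs "), r = NA_real_,
                        p = NA_real_, test_used = NA_character_,
                        n = sum(ok), flag = "zero_variance",
                        stringsAsFactors = FALSE))
    ct <- gated_correlation(a, b)
    data.frame(pair = paste(pr, collapse = " vs "), r = ct$r, p = ct$p,
               test_used = ct$test_used, n = ct$n, flag = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
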