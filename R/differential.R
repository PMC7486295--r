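#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test for a difference between two samples. When both groups have
#' at most `exact_max` observations the two-sided p-value is computed by
#' full enumeration of all `choose(n1 + n2, n1)` group assignments of the
#' pooled values (ties handled naturally through midranks); otherwise the
#' tie-corrected normal approximation (without continuity correction) is
#' used. The statistic `U` is reported for the first sample.
#'
#' @param x,y numeric vectors
#' @param exact_max exact-enumeration bound on each group size, default 8
#' @return list with `U`, `p`, `method` (`"exact"`/`"normal"`)
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_stat <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(n1 + n2, n1)
    u_all <- apply(idx, 2, function(ii)
      sum(r[ii]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(u_stat - mu) - 1e-12)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    sig2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sig2 <= 0) { p <- 1 } else {
      z <- (u_stat - mu) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal"
  }
  list(U = u_stat, p = p, method = method)
}

#' Median split of cells by OR count
#'
#' The global median `m` of the per-cell OR count is computed once across all
#' cells; within each cluster, cells with `or_count > m` are labelled `high`
#' and the rest `low`. Clusters falling entirely on one side are flagged for
#' exclusion from differential expression (with a warning), not errors.
#'
#' @param profile a `repertoire_profile`
#' @param clusters per-cell cluster labels aligned with the profile
#' @return `data.frame` with columns `cell_id`, `cluster`, `or_count`,
#'   `group`; attribute `excluded_clusters` lists one-sided clusters and
#'   attribute `median` carries the global median
#' @export
median_split <- function(profile, clusters) {
  stopifnot(inherits(profile, "repertoire_profile"))
  if (length(clusters) != nrow(profile))
    stop("clusters must align with the profile cells")
  m <- median(profile$or_count)
  group <- ifelse(profile$or_count > m, "high", "low")
  out <- data.frame(cell_id = profile$cell_id,
                    cluster = as.character(clusters),
                    or_count = profile$or_count,
                    group = group, stringsAsFactors = FALSE)
  one_sided <- vapply(split(group, out$cluster),
                      function(g) length(unique(g)) < 2, TRUE)
  excluded <- names(one_sided)[one_sided]
  if (length(excluded))
    warning("cluster(s) entirely on one side of the median, excluded from ",
            "differential expression: ", paste(excluded, collapse = ", "))
  attr(out, "excluded_clusters") <- excluded
  attr(out, "median") <- m
  out
}

#' Mann-Whitney differential expression between two cell groups
#'
#' Per gene: a two-sided Mann-Whitney test on TPM values plus a
#' pseudocounted linear fold change `FC = (mean_high + 1) / (mean_low + 1)`.
#' A gene passes when `FC >= fc_cutoff` or `FC <= 1/fc_cutoff` and
#' `p < p_cutoff` (raw p; a Benjamini-Hochberg column is reported but not
#' gated on).
#'
#' @param matrix a TPM `expression_matrix`
#' @param labels per-cell labels, values `"high"`/`"low"`, aligned with the
#'   matrix columns; other labels (e.g. excluded clusters) are dropped
#' @param fc_cutoff linear fold-change gate, default 4
#' @param p_cutoff raw p-value gate, default 0.05
#' @return `data.frame` of class `de_table`: `gene`, `mean_high`,
#'   `mean_low`, `fc`, `log2fc`, `p`, `p_bh`, `pass`
#' @export
wilcoxon_de <- function(matrix, labels, fc_cutoff = 4, p_cutoff = 0.05) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (length(labels) != ncol(matrix$values))
    stop("labels must align with matrix columns")
  hi <- which(labels == "high"); lo <- which(labels == "low")
  if (length(hi) < 3 || length(lo) < 3)
    stop("need >= 3 cells in each of the high and low groups")
  v <- matrix$values
  res <- t(vapply(seq_len(nrow(v)), function(i) {
    xh <- v[i, hi]; xl <- v[i, lo]
    mw <- mann_whitney_u(xh, xl)
    c(mean(xh), mean(xl), mw$p)
  }, c(0, 0, 0)))
  fc <- (res[, 1] + 1) / (res[, 2] + 1)
  out <- data.frame(gene = rownames(v),
                    mean_high = res[, 1], mean_low = res[, 2],
                    fc = fc, log2fc = log2(fc), p = res[, 3],
                    p_bh = p.adjust(res[, 3], "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$pass <- (out$fc >= fc_cutoff | out$fc <= 1 / fc_cutoff) &
    out$p < p_cutoff
  class(out) <- c("de_table", "data.frame")
  out
}

#' One-vs-rest cluster markers
#'
#' For each cluster, the same rank-sum statistic as [wilcoxon_de()] against
#' all remaining cells, with the conventional marker gate (fold change >= 2,
#' p < 0.05) rather than the stricter differential-expression gate.
#' Singleton clusters are skipped with a warning.
#'
#' @param matrix a TPM `expression_matrix`
#' @param clusters per-cell cluster labels
#' @param fc_cutoff marker fold-change gate, default 2
#' @param p_cutoff marker p gate, default 0.05
#' @return named list of `de_table`s, one per retained cluster; `fc > 1`
#'   means up in the cluster
#' @export
cluster_markers <- function(matrix, clusters, fc_cutoff = 2,
                            p_cutoff = 0.05) {
  stopifnot(inherits(matrix, "expression_matrix"))
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(matrix$values))
    stop("clusters must align with matrix columns")
  ids <- sort(unique(clusters))
  if (length(ids) < 2) stop("need >= 2 clusters for one-vs-rest markers")
  out <- list()
  for (k in ids) {
    if (sum(clusters == k) < 3 || sum(clusters != k) < 3) {
      warning("cluster ", k, " too small for markers, skipped")
      next
    }
    labels <- ifelse(clusters == k, "high", "low")
    out[[k]] <- wilcoxon_de(matrix, labels, fc_cutoff = fc_cutoff,
                            p_cutoff = p_cutoff)
  }
  out
}
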