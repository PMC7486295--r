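#' Score cells for doublet likelihood
#'
#' A deliberately compact simulated-doublet classifier: (1) log2(TPM+1);
#' (2) PCA of the observed cells to `n_pcs`; (3) `ceiling(sim_ratio * n)`
#' synthetic doublets formed as random-pair TPM means and projected into the
#' same PC space; (4) for each observed cell, the fraction `f` of its `k`
#' Euclidean nearest neighbours (among observed + simulated, ties broken by
#' column index) that are simulated; (5) score
#' `(f/rho) / ((f/rho) + (1 - f))` with `rho = sim_ratio / (1 + sim_ratio)`
#' correcting the observed/simulated class imbalance. There is no
#' variance-stabilization, gene selection or expected-rate prior: the aim is
#' recovering concatenated cells, not score-level parity with heavier tools.
#'
#' @param matrix a TPM `expression_matrix` with at least `max(2k, 50)` cells
#' @param n_pcs number of principal components (must be < number of cells)
#' @param k neighbourhood size
#' @param sim_ratio simulated doublets per observed cell
#' @param seed integer seed (doublet pair sampling)
#' @return a `data.frame` of class `doublet_report` with columns `cell_id`,
#'   `score`, and attributes `n_simulated`, `k`, `n_pcs`, `sim_ratio`, `seed`
#' @export
score_doublets <- function(matrix, n_pcs = 30L, k = 20L, sim_ratio = 1,
                           seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  n <- ncol(matrix$values)
  if (n < max(2L * k, 50L))
    stop("need at least max(2k, 50) = ", max(2L * k, 50L), " cells, have ", n)
  if (n_pcs >= n) stop("n_pcs must be smaller than the number of cells")
  if (sim_ratio < 0) stop("sim_ratio must be >= 0")
  tpm <- if (matrix$scale == "TPM") matrix$values else 2^matrix$values - 1
  x_obs <- t(log2(tpm + 1))                      # cells x genes
  pca <- prcomp(x_obs, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb_obs <- pca$x

  n_sim <- ceiling(sim_ratio * n)
  if (n_sim > 0) {
    set.seed(seed)
    p1 <- sample.int(n, n_sim, replace = TRUE)
    p2 <- (p1 + sample.int(n - 1L, n_sim, replace = TRUE) - 1L) %% n + 1L
    dbl_tpm <- (tpm[, p1, drop = FALSE] + tpm[, p2, drop = FALSE]) / 2
    x_sim <- t(log2(dbl_tpm + 1))
    emb_sim <- sweep(x_sim, 2, pca$center) %*% pca$rotation
    emb_all <- rbind(emb_obs, emb_sim)
  } else {
    emb_all <- emb_obs
  }
  is_sim <- c(rep(FALSE, n), rep(TRUE, nrow(emb_all) - n))

  # squared Euclidean distances observed -> all, via the norm expansion
  nrm_all <- rowSums(emb_all^2)
  d2 <- outer(rowSums(emb_obs^2), nrm_all, "+") -
    2 * emb_obs %*% t(emb_all)
  rho <- if (sim_ratio > 0) sim_ratio / (1 + sim_ratio) else NA_real_
  f <- vapply(seq_len(n), function(i) {
    d <- d2[i, ]
    d[i] <- Inf                                   # exclude self
    nb <- order(d, seq_along(d))[seq_len(k)]      # ties by index order
    mean(is_sim[nb])
  }, 0)
  score <- if (n_sim == 0) rep(0, n) else {
    num <- f / rho
    num / (num + (1 - f))
  }
  out <- data.frame(cell_id = colnames(matrix$values), score = score,
                    stringsAsFactors = FALSE)
  attr(out, "n_simulated") <- as.integer(if (n_sim > 0) n_sim else 0L)
  attr(out, "k") <- as.integer(k)
  attr(out, "n_pcs") <- as.integer(n_pcs)
  attr(out, "sim_ratio") <- sim_ratio
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("doublet_report", "data.frame")
  out
}

#' Otsu's threshold on a score histogram
#'
#' @param scores numeric vector in `[0, 1]`
#' @param n_bins histogram bins
#' @return threshold in `[0, 1]`; for a degenerate (zero-variance) histogram
#'   a threshold above every score is returned, so nothing is called
#' @keywords internal
otsu_threshold <- function(scores, n_bins = 256L) {
  if (length(unique(scores)) < 2) return(min(max(scores) + 1e-9, 1))
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- tabulate(findInterval(scores, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sb2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  breaks[which.max(sb2) + 1L]
}

#' Call doublets from a score report and filter the matrix
#'
#' A cell is a doublet iff `score >= threshold`. `threshold = "auto"` applies
#' Otsu's between-class-variance threshold to the score histogram.
#'
#' @param report a `doublet_report` from [score_doublets()]
#' @param matrix the `expression_matrix` the report was computed on
#' @param threshold numeric in `[0, 1]`, or `"auto"`
#' @return list with `report` (the input plus a `call` column and a
#'   `threshold` attribute) and `matrix` (the singlet-only matrix)
#' @export
call_doublets <- function(report, matrix, threshold = "auto") {
  stopifnot(inherits(report, "doublet_report"),
            inherits(matrix, "expression_matrix"))
  if (!identical(report$cell_id, colnames(matrix$values)))
    stop("report and matrix disagree on cell identities")
  thr <- if (identical(threshold, "auto")) otsu_threshold(report$score)
         else as.numeric(threshold)
  if (!identical(threshold, "auto") && (thr < 0 || thr > 1))
    stop("threshold must lie in [0, 1]")
  call <- ifelse(report$score >= thr, "doublet", "singlet")
  report$call <- call
  attr(report, "threshold") <- thr
  keep <- call == "singlet"
  list(report = report,
       matrix = subset_samples(matrix, keep))
}
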