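# Shared fixtures and small oracles, built in code at test time.

# adjusted Rand index (independent of any package clustering internals)
ari <- function(a, b) {
  t <- table(a, b); n <- sum(t)
  s <- function(x) sum(choose(x, 2))
  exp_ <- s(rowSums(t)) * s(colSums(t)) / choose(n, 2)
  (s(t) - exp_) / ((s(rowSums(t)) + s(colSums(t))) / 2 - exp_)
}

# small dense expression matrix with unique names
toy_matrix <- function(values, scale = "TPM") {
  if (is.null(dimnames(values)))
    dimnames(values) <- list(paste0("G", seq_len(nrow(values))),
                             paste0("c", seq_len(ncol(values))))
  expression_matrix(values, scale = scale)
}

# TPM renormalization without touching package internals
renorm <- function(v) sweep(v, 2, colSums(v) / 1e6, "/")

# a small mixed-family catalog for io tests
toy_catalog <- function() {
  gene_catalog(symbol = c("OR1A1", "OR2M3", "OR5P2", "OR7D4", "TAAR5",
                          "TAS2R38"),
               family = c("OR", "OR", "OR", "OR", "TAAR", "T2R"),
               chromosome = c("chr17", "chr14", "chr11", "chr19", "chr6",
                              "chr7"),
               status = c("functional", "functional", "pseudogene",
                          "functional", "functional", "functional"))
}

# two well-separated cell populations in TPM space (for clustering tests)
two_blob_matrix <- function(n_per = 200, n_genes = 60, shift = 3,
                            sd = 0.5, seed = 9) {
  set.seed(seed)
  base <- matrix(rnorm(2 * n_per * n_genes, 5, sd), n_genes, 2 * n_per)
  half <- n_genes %/% 2
  base[seq_len(half), seq_len(n_per)] <-
    base[seq_len(half), seq_len(n_per)] + shift
  base[(half + 1):n_genes, (n_per + 1):(2 * n_per)] <-
    base[(half + 1):n_genes, (n_per + 1):(2 * n_per)] + shift
  v <- 2^base
  dimnames(v) <- list(paste0("G", seq_len(n_genes)),
                      paste0("c", seq_len(2 * n_per)))
  list(matrix = expression_matrix(renorm(v), scale = "TPM"),
       truth = rep(1:2, each = n_per))
}

# brute-force Mann-Whitney two-sided p by direct enumeration of group
# assignments, computing U from pairwise comparisons (not ranks)
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(ii) {
    a <- pooled[ii]; b <- pooled[-ii]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# product-limit recomputation that re-derives risk sets at every event time
km_brute_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_i <- sum(time >= ts[i])
    d_i <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  data.frame(time = ts, survival = out)
}

# per-event-time hypergeometric log-rank oracle for two groups
logrank_oracle_2g <- function(time, event, group) {
  gs <- sort(unique(group))
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v1 <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == gs[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == gs[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v1 <- v1 + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / v1
}
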