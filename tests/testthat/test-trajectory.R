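test_that("two well-separated populations give exactly two clusters", {
  blobs <- two_blob_matrix(n_per = 200, n_genes = 60, seed = 9)
  emb <- embed_and_cluster(blobs$matrix, n_pcs = 10, k_nn = 30)
  expect_equal(length(unique(emb$clusters)), 2L)
  expect_equal(ari(emb$clusters, blobs$truth), 1.0)
  # duplicated cells land in the same cluster
  v <- blobs$matrix$values
  dup <- expression_matrix(cbind(v, `dup1` = v[, 1]), scale = "TPM")
  emb2 <- embed_and_cluster(dup, n_pcs = 10, k_nn = 30)
  expect_equal(unname(emb2$clusters["dup1"]), unname(emb2$clusters["c1"]))
})

test_that("zero-variance input cannot be embedded", {
  v <- matrix(5, 40, 50, dimnames = list(paste0("G", 1:40),
                                         paste0("c", 1:50)))
  m <- expression_matrix(v, scale = "TPM")
  expect_error(embed_and_cluster(m, n_pcs = 5, k_nn = 5), "zero variance")
})

test_that("root selection maximizes mean stemness with deterministic ties", {
  emb <- structure(list(
    embedding = matrix(c(0, 0, 0, 1, 1, 1, 5, 5.2, 5.4, 9, 9.1, 9.2),
                       ncol = 1,
                       dimnames = list(paste0("c", 1:12), "PC1")),
    clusters = setNames(rep(1:3, each = 4), paste0("c", 1:12)),
    n_components = 1L), class = "cell_embedding")
  stem <- setNames(c(rep(0.1, 4), rep(0.9, 4), rep(0.4, 4)),
                   paste0("c", 1:12))
  root <- select_root(emb, stem)
  expect_equal(root$root_cluster, 2L)
  expect_true(root$root_cell %in% paste0("c", 5:8))

  tie <- setNames(c(rep(0.9, 4), rep(0.9, 4), rep(0.1, 4)),
                  paste0("c", 1:12))
  expect_warning(rt <- select_root(emb, tie), "tie")
  expect_equal(rt$root_cluster, 1L)

  single <- emb
  single$clusters <- setNames(rep(1L, 12), paste0("c", 1:12))
  expect_equal(select_root(single, stem)$root_cluster, 1L)
})

test_that("pseudotime on a chain is monotone, zero at root, max one", {
  emb <- matrix(seq(0, 10, length.out = 21), ncol = 1,
                dimnames = list(paste0("c", 1:21), "PC1"))
  pt <- compute_pseudotime(emb, "c1", k_nn = 2)
  expect_equal(unname(pt["c1"]), 0)
  expect_equal(max(pt), 1)
  expect_true(all(diff(pt) > 0))
  # geodesic on the chain equals cumulative (here linear) distance
  expect_equal(as.numeric(pt), seq(0, 1, length.out = 21),
               tolerance = 1e-12)
})

test_that("pseudotime is invariant under rigid rotation of the embedding", {
  set.seed(44)
  emb <- matrix(rnorm(120), 60, 2, dimnames = list(paste0("c", 1:60), NULL))
  theta <- 0.83
  rot <- emb %*% matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)),
                        2, 2)
  rownames(rot) <- rownames(emb)
  pt1 <- compute_pseudotime(emb, "c5", k_nn = 6)
  pt2 <- compute_pseudotime(rot, "c5", k_nn = 6)
  expect_equal(unname(pt1), unname(pt2), tolerance = 1e-9)
})

test_that("pseudotime equals an independent geodesic and obeys the triangle inequality", {
  set.seed(45)
  emb <- matrix(rnorm(100), 50, 2, dimnames = list(paste0("c", 1:50), NULL))
  k <- 5
  pt <- compute_pseudotime(emb, "c1", k_nn = k)
  expect_length(attr(pt, "unreachable"), 0)

  # independent Bellman-Ford-style relaxation over the union kNN graph
  d <- as.matrix(dist(emb))
  adj <- matrix(FALSE, 50, 50)
  for (i in 1:50) {
    nb <- order(d[i, ], seq_len(50))[2:(k + 1)]
    adj[i, nb] <- TRUE; adj[nb, i] <- TRUE
  }
  geo <- rep(Inf, 50); geo[1] <- 0
  repeat {
    changed <- FALSE
    for (i in 1:50) for (j in which(adj[i, ])) {
      cand <- geo[j] + d[i, j]
      if (cand < geo[i] - 1e-15) { geo[i] <- cand; changed <- TRUE }
    }
    if (!changed) break
  }
  expect_equal(as.numeric(pt), geo / max(geo), tolerance = 1e-9)
  # triangle inequality on every graph edge (unscaled geodesics)
  for (i in 1:50) for (j in which(adj[i, ]))
    expect_lte(geo[i], geo[j] + d[i, j] + 1e-9)
})

test_that("stemness equal to 1 - pseudotime correlates at exactly -1", {
  set.seed(46)
  emb <- matrix(c(sort(runif(40, 0, 10))), ncol = 1,
                dimnames = list(paste0("c", 1:40), "PC1"))
  pt <- compute_pseudotime(emb, "c1", k_nn = 3)
  prof <- structure(data.frame(cell_id = names(pt),
                               or_count = rpois(40, 3),
                               mean_or_expression = runif(40)),
                    class = c("repertoire_profile", "data.frame"))
  tab <- pseudotime_correlations(pt, 1 - pt, prof)
  row <- tab[tab$pair == "pseudotime vs stemness", ]
  expect_equal(row$r, -1, tolerance = 1e-9)
  # zero-variance variable is flagged, not an error
  prof$or_count <- 2L
  tab2 <- pseudotime_correlations(pt, 1 - pt, prof)
  expect_equal(tab2$flag[tab2$pair == "pseudotime vs or_count"],
               "zero_variance")
})
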