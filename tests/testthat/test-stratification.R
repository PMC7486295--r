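test_that("cosine similarity matches its defining formula", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1,
               tolerance = 1e-12)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 2, 3), c(4, 5, 6)),
               32 / sqrt(14 * 77), tolerance = 1e-9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:3, 1:4), "equal length")
  # scale invariance
  set.seed(1)
  a <- runif(30); b <- runif(30)
  for (alpha in c(1e-6, 0.5, 7, 1e6))
    expect_equal(cosine_similarity(alpha * a, b), cosine_similarity(a, b),
                 tolerance = 1e-12)
})

make_or_fixture <- function(n_per = 30, seed = 64) {
  # two cell populations with disjoint active-OR sets
  set.seed(seed)
  ors <- paste0("OR", 1:10, "A1")
  act <- matrix(0L, 10, 2 * n_per,
                dimnames = list(ors, paste0("c", seq_len(2 * n_per))))
  for (j in seq_len(n_per)) act[sample(1:5, 2), j] <- 1L
  for (j in (n_per + 1):(2 * n_per)) act[sample(6:10, 3), j] <- 1L
  attr(act, "threshold") <- -3
  class(act) <- c("activation_matrix", class(act))
  v <- (act == 1L) * 2^matrix(rnorm(length(act), 8, 0.5), 10, 2 * n_per)
  dimnames(v) <- dimnames(act)
  list(act = act, expr = expression_matrix(v, scale = "TPM"),
       truth = rep(1:2, each = n_per))
}

test_that("signatures from disjoint OR populations separate cleanly", {
  f <- make_or_fixture()
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 2)
  expect_equal(ari(sigs$cell_cluster, f$truth), 1.0)
  # each signature supported only on its population's receptors
  s <- sigs$signatures
  pop_of <- sigs$cell_cluster[1]  # cluster id of population 1
  sig_pop1 <- s[, paste0("signature", pop_of)]
  expect_true(all(sig_pop1[6:10] == 0))
  expect_true(any(sig_pop1[1:5] > 0))
  # mean OR count annotation: population 1 planted 2, population 2 planted 3
  mk <- sigs$meta$mean_or_count[order(sigs$meta$cluster)]
  expect_setequal(round(mk, 6), c(2, 3))
})

test_that("n_clusters = n_cells reproduces each cell exactly", {
  f <- make_or_fixture(n_per = 4)
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 8)
  lg <- log2(f$expr$values + 1)
  for (j in 1:8) {
    k <- sigs$cell_cluster[j]
    expect_equal(unname(sigs$signatures[, paste0("signature", k)]),
                 unname(lg[, j]), tolerance = 1e-12)
  }
})

test_that("identical binary profiles degenerate to a single cluster", {
  act <- matrix(1L, 3, 10, dimnames = list(paste0("OR", 1:3, "A1"),
                                           paste0("c", 1:10)))
  attr(act, "threshold") <- -3
  class(act) <- c("activation_matrix", class(act))
  v <- matrix(8, 3, 10, dimnames = dimnames(act))
  m <- expression_matrix(v, scale = "TPM")
  expect_error(build_or_signatures(m, act, n_clusters = 2), "cannot form")
})

test_that("projection: self-similarity 1, bounds, flags and missing genes", {
  f <- make_or_fixture()
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 2)
  # bulk columns equal to the signatures themselves (back-transformed)
  bulk_v <- 2^sigs$signatures - 1
  bulk_v <- cbind(bulk_v, zero_patient = 0)
  colnames(bulk_v) <- c("p1", "p2", "pzero")
  bulk <- expression_matrix(bulk_v, scale = "TPM")
  expect_warning(sm <- project_signatures(bulk, sigs), "all-zero")
  expect_equal(unname(diag(sm[1:2, 1:2])), c(1, 1), tolerance = 1e-9)
  expect_true(all(sm[1:2, ] >= 0 & sm[1:2, ] <= 1))
  expect_true(all(is.na(sm["pzero", ])))

  # missing OR genes are zero-filled with a warning
  bulk2 <- expression_matrix(bulk_v[1:6, 1:2, drop = FALSE], scale = "TPM")
  expect_warning(   # few shared genes also draws an instability warning
    expect_warning(sm2 <- project_signatures(bulk2, sigs),
                   "absent from bulk"),
    "unstable")
  expect_equal(attr(sm2, "n_shared_genes"), 6L)

  none <- expression_matrix(matrix(1, 2, 2, dimnames = list(c("A", "B"),
                                                            c("p1", "p2"))),
                            scale = "TPM")
  expect_error(suppressWarnings(project_signatures(none, sigs)), "shared")
})

test_that("one-hot bulk mixtures recover their signature by argmax", {
  f <- make_or_fixture()
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 2)
  cfg <- sim_config(seed = 30, n_patients = 40L, mixture_alpha = 0.001,
                    bulk_noise_sd = 0, censoring_rate = 0,
                    hazards = c(0.3, 0.1))
  sig_tpm <- 2^sigs$signatures - 1
  coh <- simulate_bulk_cohort(sig_tpm, cfg)
  sm <- suppressWarnings(project_signatures(coh$bulk, sigs))
  am <- apply(sm, 1, which.max)
  expect_equal(unname(am), unname(coh$truth_group))
})

test_that("patient stratification recovers planted dominance groups", {
  f <- make_or_fixture()
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 2)
  cfg <- sim_config(seed = 31, n_patients = 100L, mixture_alpha = 0.02,
                    bulk_noise_sd = 0.1, hazards = c(0.3, 0.1))
  sig_tpm <- 2^sigs$signatures - 1
  coh <- simulate_bulk_cohort(sig_tpm, cfg)
  sm <- suppressWarnings(project_signatures(coh$bulk, sigs))
  grp <- stratify_patients(sm, n_groups = 2)
  expect_gte(ari(grp[names(coh$truth_group)], coh$truth_group), 0.9)

  # duplicated patients share a group
  sm_dup <- rbind(sm, sm)
  rownames(sm_dup) <- c(rownames(sm), paste0(rownames(sm), "_dup"))
  class(sm_dup) <- class(sm)
  g2 <- stratify_patients(sm_dup, n_groups = 2)
  expect_identical(unname(g2[seq_len(nrow(sm))]),
                   unname(g2[nrow(sm) + seq_len(nrow(sm))]))

  # single group is a no-op
  g1 <- stratify_patients(sm, n_groups = 1)
  expect_true(all(g1 == "group1"))
  expect_error(stratify_patients(sm, n_groups = 1000), "more groups")
})

test_that("similarity matrix is equivariant to patient and signature order", {
  f <- make_or_fixture()
  sigs <- build_or_signatures(f$expr, f$act, n_clusters = 2)
  bulk_v <- 2^sigs$signatures - 1 + 5
  colnames(bulk_v) <- c("p1", "p2")
  bulk <- expression_matrix(bulk_v, scale = "TPM")
  sm <- project_signatures(bulk, sigs)
  bulk_rev <- expression_matrix(bulk_v[, 2:1], scale = "TPM")
  sm_rev <- project_signatures(bulk_rev, sigs)
  expect_equal(unclass(sm_rev), unclass(sm)[2:1, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
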