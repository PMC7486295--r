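test_that("exact Mann-Whitney p matches enumeration for small groups", {
  # canonical case: {1,2} vs {3,4} -> U = 0, two-sided p = 1/3
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$method, "exact")

  set.seed(14)
  for (i in 1:15) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)   # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, mw_enum_oracle(x, y), tolerance = 1e-12,
                 info = paste("case", i))
  }
  # tie-free cases also agree with the base-R exact test
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(5)
    got <- mann_whitney_u(x, y)
    expect_equal(got$p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("large groups fall back to the tie-corrected normal approximation", {
  set.seed(2)
  x <- rnorm(30); y <- rnorm(40, 1)
  got <- mann_whitney_u(x, y)
  expect_equal(got$method, "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(got$p, ref, tolerance = 1e-9)
})

test_that("median split uses a single global median applied within clusters", {
  prof <- structure(data.frame(cell_id = paste0("c", 1:4),
                               or_count = c(0L, 1L, 2L, 3L),
                               mean_or_expression = 0),
                    class = c("repertoire_profile", "data.frame"))
  sp <- median_split(prof, rep("A", 4))
  expect_equal(attr(sp, "median"), 1.5)
  expect_equal(sp$group, c("low", "low", "high", "high"))

  prof$or_count <- rep(2L, 4)
  expect_warning(sp2 <- median_split(prof, rep("A", 4)), "one side")
  expect_true(all(sp2$group == "low"))
  expect_equal(attr(sp2, "excluded_clusters"), "A")

  # identical per-cluster distributions give identical split proportions
  prof3 <- structure(data.frame(cell_id = paste0("c", 1:8),
                                or_count = rep(c(0L, 1L, 2L, 3L), 2),
                                mean_or_expression = 0),
                     class = c("repertoire_profile", "data.frame"))
  sp3 <- median_split(prof3, rep(c("A", "B"), each = 4))
  expect_equal(mean(sp3$group[sp3$cluster == "A"] == "high"),
               mean(sp3$group[sp3$cluster == "B"] == "high"))
})

test_that("fold change uses pseudocounted means and the +-4 gate", {
  v <- rbind(planted = c(rep(39, 4), rep(9, 4)),
             flat = rep(10, 8),
             down = c(rep(9, 4), rep(39, 4)))
  colnames(v) <- paste0("c", 1:8)
  m <- expression_matrix(v, scale = "TPM")
  labels <- rep(c("high", "low"), each = 4)
  de <- suppressWarnings(wilcoxon_de(m, labels))
  expect_equal(de$fc[de$gene == "planted"], 4)        # (39+1)/(9+1)
  expect_equal(de$fc[de$gene == "down"], 1 / 4)
  # group-swap symmetry: FC -> 1/FC
  de_sw <- suppressWarnings(wilcoxon_de(m, rev(labels)))
  expect_equal(de_sw$fc[de_sw$gene == "planted"],
               1 / de$fc[de$gene == "planted"])
  # identical groups: nothing passes
  v2 <- matrix(rep(c(5, 8, 2, 5, 8, 2), 3), 3, 6, byrow = TRUE)
  dimnames(v2) <- list(paste0("g", 1:3), paste0("c", 1:6))
  de2 <- suppressWarnings(
    wilcoxon_de(expression_matrix(v2, scale = "TPM"),
                rep(c("high", "low"), each = 3)))
  expect_false(any(de2$pass))
})

test_that("pass set is monotone in p_cutoff and anti-monotone in fc_cutoff", {
  set.seed(77)
  v <- 2^matrix(rnorm(50 * 30, 5, 1), 50, 30)
  v[1:10, 1:15] <- v[1:10, 1:15] * 8
  dimnames(v) <- list(paste0("g", 1:50), paste0("c", 1:30))
  m <- expression_matrix(v, scale = "TPM")
  labels <- rep(c("high", "low"), each = 15)
  n_pass <- function(fc, p) sum(wilcoxon_de(m, labels, fc, p)$pass)
  expect_lte(n_pass(4, 0.01), n_pass(4, 0.05))
  expect_lte(n_pass(8, 0.05), n_pass(4, 0.05))
})

test_that("cluster markers recover planted cluster-specific genes", {
  set.seed(123)
  n <- 60
  v <- 2^matrix(rnorm(20 * 3 * n, 5, 0.5), 20, 3 * n)
  cl <- rep(c("A", "B", "C"), each = n)
  v[1, cl == "A"] <- v[1, cl == "A"] * 50
  v[2, cl == "B"] <- v[2, cl == "B"] * 50
  v[3, cl == "C"] <- v[3, cl == "C"] * 50
  dimnames(v) <- list(paste0("g", 1:20), paste0("c", seq_len(3 * n)))
  m <- expression_matrix(renorm(v), scale = "TPM")
  mk <- cluster_markers(m, cl)
  top_of <- function(k) mk[[k]]$gene[which.max(mk[[k]]$log2fc *
                                                 (mk[[k]]$pass))]
  expect_equal(top_of("A"), "g1")
  expect_equal(top_of("B"), "g2")
  expect_equal(top_of("C"), "g3")

  expect_warning(cluster_markers(m, c("solo", cl[-1])), "too small")
  expect_error(cluster_markers(m, rep("A", 3 * n)), ">= 2 clusters")
})

test_that("label permutation yields no markers at the gate almost always", {
  set.seed(55)
  v <- 2^matrix(rnorm(30 * 40, 5, 1), 30, 40)
  dimnames(v) <- list(paste0("g", 1:30), paste0("c", 1:40))
  m <- expression_matrix(renorm(v), scale = "TPM")
  hits <- 0
  for (i in 1:30) {
    labels <- sample(rep(c("high", "low"), each = 20))
    de <- wilcoxon_de(m, labels, fc_cutoff = 2)
    hits <- hits + any(de$pass)
  }
  expect_lte(hits / 30, 0.05 + 0.15)  # >= 95% permutation nulls marker-free
})
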