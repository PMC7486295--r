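# independent step-by-step reference for the set-scoring random walk,
# written as explicit loops over the algorithm's four stages
gsva_reference <- function(x, members, tau = 1) {
  ng <- nrow(x); ns <- ncol(x)
  kcdf <- matrix(0, ng, ns)
  for (i in seq_len(ng)) {
    bw <- max(sd(x[i, ]) / 4, 1e-8)
    for (j in seq_len(ns)) {
      acc <- 0
      for (jp in seq_len(ns)) acc <- acc + pnorm((x[i, j] - x[i, jp]) / bw)
      kcdf[i, j] <- acc / ns
    }
  }
  out <- numeric(ns)
  mem_idx <- which(rownames(x) %in% members)
  for (j in seq_len(ns)) {
    ord <- order(-kcdf[, j], seq_len(ng))
    centered <- (ng + 1) / 2 - seq_len(ng)
    wsum <- sum(abs(centered[match(mem_idx, ord)])^tau)
    walk <- 0; mx <- 0; mn <- 0
    for (pos in seq_len(ng)) {
      gene <- ord[pos]
      if (gene %in% mem_idx)
        walk <- walk + abs(centered[pos])^tau / wsum
      else
        walk <- walk - 1 / (ng - length(mem_idx))
      mx <- max(mx, walk); mn <- min(mn, walk)
    }
    out[j] <- mx + mn
  }
  out
}

tiny_instance <- function() {
  set.seed(60)
  x <- matrix(rnorm(24, 5, 2), 6, 4,
              dimnames = list(paste0("G", 1:6), paste0("s", 1:4)))
  list(m = expression_matrix(abs(x), scale = "LOG2_TPM1"),
       set = list(myset = c("G2", "G5")))
}

test_that("tiny-instance scores match the step-by-step reference", {
  ti <- tiny_instance()
  got <- gsva_scores(ti$m, ti$set)
  ref <- gsva_reference(ti$m$values, ti$set$myset)
  expect_equal(unname(got["myset", ]), ref, tolerance = 1e-9)
})

test_that("identical sample columns receive identical scores", {
  ti <- tiny_instance()
  v <- ti$m$values
  v[, 2] <- v[, 1]
  m <- expression_matrix(v, scale = "LOG2_TPM1")
  sc <- gsva_scores(m, ti$set)
  expect_equal(sc["myset", 1], sc["myset", 2], tolerance = 1e-12)
})

test_that("scores are invariant to gene order and per-gene location shifts", {
  ti <- tiny_instance()
  base <- gsva_scores(ti$m, ti$set)
  perm <- expression_matrix(ti$m$values[c(4, 2, 6, 1, 5, 3), ],
                            scale = "LOG2_TPM1")
  expect_equal(unclass(gsva_scores(perm, ti$set)), unclass(base),
               tolerance = 1e-12, ignore_attr = TRUE)
  shifted <- ti$m$values
  shifted[3, ] <- shifted[3, ] + 4.2
  sm <- expression_matrix(shifted, scale = "LOG2_TPM1")
  expect_equal(unclass(gsva_scores(sm, ti$set)), unclass(base),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a planted up-shifted gene set scores higher in shifted samples", {
  wins <- 0
  for (seed in 1:20) {
    set.seed(seed)
    v <- matrix(rnorm(40 * 20, 5, 1), 40, 20,
                dimnames = list(paste0("G", 1:40), paste0("s", 1:20)))
    v[1:8, 11:20] <- v[1:8, 11:20] + 3
    m <- expression_matrix(abs(v), scale = "LOG2_TPM1")
    sc <- gsva_scores(m, list(planted = paste0("G", 1:8)))
    wins <- wins + (mean(sc["planted", 11:20]) > mean(sc["planted", 1:10]))
  }
  expect_gte(wins, 19)  # sign test p < 0.01 under a fair coin
})

test_that("empty sets are dropped with a warning; full coverage errors", {
  ti <- tiny_instance()
  expect_warning(sc <- gsva_scores(ti$m, list(myset = c("G2", "G5"),
                                              ghost = c("NOPE"))),
                 "dropping")
  expect_equal(rownames(sc), "myset")
  expect_error(suppressWarnings(gsva_scores(ti$m, list(ghost = "NOPE"))),
               "no gene set")
  expect_error(gsva_scores(ti$m, list(all = paste0("G", 1:6))),
               "non-members")
})

test_that("OR-pathway correlations report direction and flag zero variance", {
  set.seed(10)
  sc <- matrix(rnorm(60), 3, 20,
               dimnames = list(c("invasion", "stemness", "hypoxia"),
                               paste0("c", 1:20)))
  class(sc) <- c("enrichment_scores", class(sc))
  ore <- rbind(OR1A1 = -sc["invasion", ] + rnorm(20, 0, 0.01),
               OR2M3 = sc["stemness", ],
               FLAT = rep(1, 20))
  colnames(ore) <- colnames(sc)
  tab <- correlate_or_pathways(sc, ore)
  expect_equal(tab$direction[tab$or_symbol == "OR1A1" &
                               tab$signature == "invasion"], -1)
  expect_equal(tab$r[tab$or_symbol == "OR2M3" &
                       tab$signature == "stemness"], 1, tolerance = 1e-9)
  expect_true(all(tab$flag[tab$or_symbol == "FLAT"] == "zero_variance"))
})
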