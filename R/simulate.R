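#' Simulation configuration
#'
#' Bundles the parameters of the synthetic single-cell / bulk generator. The
#' generator emulates the structure the analysis assumes: sparse non-negative
#' TPM with a zero spike, discrete cluster structure, a latent differentiation
#' time `t ~ Uniform(0,1)` with stemness `s = 1 - t + Normal(0, stemness_sd)`
#' (stemness falls along differentiation), a per-cell expressed-OR count
#' `K ~ Poisson(max(0, or_rate_base + or_stemness_slope * s))` with OR
#' identities drawn without replacement — stochastically, but with a
#' configurable bias towards a cluster-specific recurrent receptor pool —
#' optional doublet contamination, and bulk profiles as Dirichlet mixtures
#' of cell-cluster signatures with group-dependent exponential survival and
#' uniform censoring.
#'
#' @param seed integer seed; the seed fully determines all generator output
#' @param n_cells number of single cells
#' @param n_background_genes non-receptor genes
#' @param n_or_functional functional OR genes in the catalog
#' @param n_or_pseudo OR pseudogenes in the catalog
#' @param n_clusters discrete cell clusters
#' @param or_rate_base mean expressed-OR count at stemness 0 (lambda0 > 0)
#' @param or_stemness_slope coupling of OR count to stemness (beta)
#' @param stemness_sd Gaussian noise sd on the stemness score
#' @param expr_mean,expr_sd log2 mean/sd of expressed-gene abundance before
#'   per-cell TPM renormalization
#' @param background_detect_rate probability a background gene at the
#'   baseline mean is expressed in a given cell (zero spike = 1 - rate)
#' @param detect_slope logistic coupling between a gene's latent log2 mean
#'   and its detection probability (expression-dependent dropout, as in real
#'   droplet data; 0 makes dropout independent of the mean)
#' @param n_program_genes genes whose mean tracks latent time: half increase
#'   with time (differentiation program), half decrease (stemness program)
#' @param program_slope log2 shift per unit latent time for program genes
#' @param n_marker_genes cluster-specific marker genes per cluster
#' @param marker_shift log2 up-shift of a marker in its own cluster
#' @param or_cluster_bias probability that each of a cell's expressed ORs is
#'   drawn from its cluster's preferred OR pool rather than uniformly from
#'   the whole functional repertoire. Receptor choice in tumors is
#'   stochastic but not exchangeable — a subset of receptors recurs across
#'   cells of a subpopulation — and this is what makes receptor-identity
#'   clustering informative; 0 gives fully uniform choice
#' @param or_pool_size preferred ORs per cluster
#' @param pseudogene_leak per-cell probability that one random OR pseudogene
#'   is expressed (pseudogenes are otherwise silent)
#' @param doublet_rate fraction of doublets appended by [inject_doublets()]
#' @param chr11_prob probability a simulated OR is placed on chromosome 11
#'   (the chromosome carrying the largest share of OR loci)
#' @param n_patients bulk cohort size
#' @param mixture_alpha Dirichlet concentration of the per-patient cluster
#'   mixture weights (small = near one-hot patients)
#' @param hazards per-group exponential hazards for the bulk cohort, recycled
#'   to the number of signatures
#' @param censoring_rate probability a patient's time is right-censored
#' @param bulk_noise_sd sd of additive Gaussian noise on bulk TPM profiles
#' @return a list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 500L,
                       n_background_genes = 400L,
                       n_or_functional = 400L,
                       n_or_pseudo = 26L,
                       n_clusters = 3L,
                       or_rate_base = 3,
                       or_stemness_slope = 0,
                       stemness_sd = 0.1,
                       expr_mean = 5,
                       expr_sd = 1.5,
                       background_detect_rate = 0.5,
                       detect_slope = 1.5,
                       n_program_genes = 100L,
                       program_slope = 3,
                       n_marker_genes = 20L,
                       marker_shift = 2,
                       or_cluster_bias = 0.8,
                       or_pool_size = 5L,
                       pseudogene_leak = 0,
                       doublet_rate = 0.05,
                       chr11_prob = 0.4,
                       n_patients = 200L,
                       mixture_alpha = 0.15,
                       hazards = c(0.9, 0.3, 0.1),
                       censoring_rate = 0.2,
                       bulk_noise_sd = 0.1) {
  cfg <- as.list(environment())
  if (cfg$or_rate_base <= 0) stop("or_rate_base must be > 0")
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  if (any(cfg$hazards <= 0)) stop("hazards must be > 0")
  if (cfg$background_detect_rate <= 0 || cfg$background_detect_rate > 1)
    stop("background_detect_rate must be in (0, 1]")
  if (cfg$or_cluster_bias < 0 || cfg$or_cluster_bias >= 1)
    stop("or_cluster_bias must be in [0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# chromosomes used for simulated receptor loci; chr11 is over-represented
.or_chromosomes <- c("chr11", "chr1", "chr3", "chr5", "chr6", "chr7",
                     "chr9", "chr12", "chr14", "chr17", "chr19")

#' Simulate a chemoreceptor catalog
#'
#' Generates `n_or_functional` functional ORs plus `n_or_pseudo` OR
#' pseudogenes with OR-nomenclature-style unique symbols and chromosome
#' assignments drawn from a fixed locus list with chromosome 11
#' over-represented at probability `chr11_prob`.
#'
#' @param config a [sim_config()]
#' @return a `gene_catalog`
#' @export
simulate_catalog <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_f <- config$n_or_functional
  n_p <- config$n_or_pseudo
  if (n_f < 1 || n_p < 0) stop("catalog counts must be positive")
  sym_f <- sprintf("OR%dA%d", seq_len(n_f), 1L + (seq_len(n_f) %% 3L))
  sym_p <- sprintf("OR%dP%d", seq_len(max(n_p, 0L)), 1L)
  other <- setdiff(.or_chromosomes, "chr11")
  draw_chrom <- function(n) ifelse(runif(n) < config$chr11_prob, "chr11",
                                   sample(other, n, replace = TRUE))
  gene_catalog(symbol = c(sym_f, sym_p),
               family = "OR",
               chromosome = draw_chrom(n_f + n_p),
               status = rep(c("functional", "pseudogene"), c(n_f, n_p)),
               or_class = ifelse(runif(n_f + n_p) < 0.1, "ClassI", "ClassII"))
}

#' Simulate single cells with a planted OR repertoire
#'
#' Draws latent time, stemness, cluster identity and a per-cell expressed-OR
#' set (see [sim_config()] for the model) and returns a TPM
#' `expression_matrix` (every cell column sums to 10^6) together with the
#' ground truth needed by the tests: per-cell `t`, `s`, planted OR count `K`,
#' cluster, the expressed-OR sets, and the program/marker gene lists.
#'
#' @param config a [sim_config()]
#' @param catalog optional pre-built catalog; regenerated from the config
#'   seed when omitted
#' @return list with elements `matrix` (`expression_matrix`, TPM), `truth`
#'   (`data.frame`: `cell_id`, `t`, `s`, `or_count`, `cluster`), `or_sets`
#'   (list of per-cell expressed functional ORs), `genes` (list with
#'   `background`, `stemness_program`, `time_program`, `markers`), and
#'   `catalog`
#' @export
simulate_cells <- function(config = sim_config(), catalog = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(catalog)) catalog <- simulate_catalog(config)
  set.seed(config$seed + 1L)
  n <- config$n_cells
  cells <- sprintf("cell%04d", seq_len(n))

  t_c <- runif(n)
  s_c <- 1 - t_c + rnorm(n, 0, config$stemness_sd)
  rate <- config$or_rate_base + config$or_stemness_slope * s_c
  if (all(rate < 0))
    stop("or_rate_base + or_stemness_slope * s is negative for every cell")
  k_c <- rpois(n, pmax(0, rate))
  cluster <- sample.int(config$n_clusters, n, replace = TRUE)

  bg <- sprintf("BG%04d", seq_len(config$n_background_genes))
  n_prog <- min(config$n_program_genes, length(bg))
  stem_prog <- bg[seq_len(n_prog %/% 2)]
  time_prog <- bg[seq_len(n_prog)[-seq_len(n_prog %/% 2)]]
  markers <- lapply(seq_len(config$n_clusters), function(k) {
    lo <- n_prog + (k - 1L) * config$n_marker_genes + 1L
    hi <- min(n_prog + k * config$n_marker_genes, length(bg))
    if (lo > length(bg)) character(0) else bg[lo:hi]
  })
  names(markers) <- paste0("cluster", seq_len(config$n_clusters))

  or_f <- catalog$symbol[catalog$status == "functional"]
  or_p <- catalog$symbol[catalog$status == "pseudogene"]
  k_c <- pmin(k_c, length(or_f))
  genes_all <- c(bg, or_f, or_p)
  vals <- matrix(0, nrow = length(genes_all), ncol = n,
                 dimnames = list(genes_all, cells))

  # per-gene log2 mean shifts along latent time / cluster
  base_mu <- matrix(config$expr_mean, length(bg), n, dimnames = list(bg, NULL))
  if (length(stem_prog))
    base_mu[stem_prog, ] <- base_mu[stem_prog, ] +
      config$program_slope * rep(0.5 - t_c, each = length(stem_prog))
  if (length(time_prog))
    base_mu[time_prog, ] <- base_mu[time_prog, ] +
      config$program_slope * rep(t_c - 0.5, each = length(time_prog))
  for (k in seq_len(config$n_clusters)) {
    mk <- markers[[k]]
    if (length(mk))
      base_mu[mk, cluster == k] <- base_mu[mk, cluster == k] +
        config$marker_shift
  }
  p_detect <- stats::plogis(stats::qlogis(config$background_detect_rate) +
                              config$detect_slope *
                                (base_mu - config$expr_mean))
  detected <- matrix(runif(length(bg) * n), length(bg), n) < p_detect
  noise <- matrix(rnorm(length(bg) * n, 0, config$expr_sd), length(bg), n)
  vals[bg, ] <- ifelse(detected, 2^(base_mu + noise), 0)

  # cluster-preferred OR pools (recurrent receptor choice)
  pools <- lapply(seq_len(config$n_clusters), function(k) {
    lo <- (k - 1L) * config$or_pool_size + 1L
    or_f[((lo:(lo + config$or_pool_size - 1L) - 1L) %% length(or_f)) + 1L]
  })
  or_sets <- vector("list", n)
  for (c_i in seq_len(n)) {
    if (k_c[c_i] > 0) {
      pool <- pools[[cluster[c_i]]]
      w <- rep((1 - config$or_cluster_bias) / length(or_f), length(or_f))
      names(w) <- or_f
      w[pool] <- w[pool] + config$or_cluster_bias / length(pool)
      chosen <- sample(or_f, k_c[c_i], prob = w)
      or_sets[[c_i]] <- chosen
      vals[chosen, c_i] <- 2^rnorm(k_c[c_i], config$expr_mean, config$expr_sd)
    } else or_sets[[c_i]] <- character(0)
    if (length(or_p) && runif(1) < config$pseudogene_leak) {
      leak <- sample(or_p, 1)
      vals[leak, c_i] <- 2^rnorm(1, config$expr_mean, config$expr_sd)
    }
  }
  vals <- tpm_normalize(vals)

  meta <- data.frame(dataset = "synthetic", condition = "tumor-tissue",
                     subtype = NA_character_,
                     cluster = as.character(cluster),
                     stringsAsFactors = FALSE)
  list(matrix = expression_matrix(vals, scale = "TPM", sample_meta = meta),
       truth = data.frame(cell_id = cells, t = t_c, s = s_c,
                          or_count = k_c, cluster = cluster,
                          stringsAsFactors = FALSE),
       or_sets = setNames(or_sets, cells),
       genes = list(background = bg, stemness_program = stem_prog,
                    time_program = time_prog, markers = markers),
       catalog = catalog)
}

#' Append synthetic doublets to a simulated dataset
#'
#' Appends `floor(rate * n)` doublets, each the per-gene mean of two distinct
#' randomly chosen parent cells in TPM space, renormalized to 10^6 (TPM is
#' compositional, so parent mean and parent sum coincide after
#' renormalization).
#'
#' @param matrix a TPM `expression_matrix`
#' @param doublet_rate fraction in `[0, 1)` of the current cell count
#' @param seed integer seed
#' @return list with `matrix` (original plus appended doublet columns) and
#'   `is_doublet` (named logical over all columns)
#' @export
inject_doublets <- function(matrix, doublet_rate, seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"), matrix$scale == "TPM")
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must be in [0, 1)")
  n <- ncol(matrix$values)
  n_dbl <- floor(doublet_rate * n)
  if (n_dbl == 0)
    return(list(matrix = matrix,
                is_doublet = setNames(rep(FALSE, n), colnames(matrix$values))))
  if (n < 2) stop("need >= 2 parent cells to form doublets")
  set.seed(seed)
  parents <- t(vapply(seq_len(n_dbl), function(i) sample.int(n, 2), c(1L, 1L)))
  dbl <- (matrix$values[, parents[, 1], drop = FALSE] +
            matrix$values[, parents[, 2], drop = FALSE]) / 2
  dbl <- tpm_normalize(dbl)
  colnames(dbl) <- sprintf("doublet%04d", seq_len(n_dbl))
  v <- cbind(matrix$values, dbl)
  meta <- matrix$sample_meta
  if (!is.null(meta)) {
    extra <- meta[rep(1, n_dbl), , drop = FALSE]
    rownames(extra) <- colnames(dbl)
    meta <- rbind(meta, extra)
  }
  list(matrix = expression_matrix(v, scale = "TPM", sample_meta = meta),
       is_doublet = setNames(c(rep(FALSE, n), rep(TRUE, n_dbl)), colnames(v)))
}

#' Simulate a bulk cohort with group-dependent survival
#'
#' Each patient's expression profile is a convex Dirichlet-weighted mixture
#' of the supplied cluster signatures (TPM scale) plus truncated Gaussian
#' noise; the patient's truth group is the argmax-weight signature. Survival
#' times are exponential with the group's hazard; with probability
#' `censoring_rate` the time is replaced by `Uniform(0, time)` and the event
#' indicator set to 0.
#'
#' @param signatures non-negative matrix, genes x signatures, TPM scale
#'   (e.g. per-cluster mean TPM profiles)
#' @param config a [sim_config()] supplying `n_patients`, `mixture_alpha`,
#'   `hazards`, `censoring_rate`, `bulk_noise_sd` and the seed
#' @return list with `bulk` (`expression_matrix`, TPM), `survival`
#'   (`survival_table`), and `truth_group` (named integer per patient)
#' @export
simulate_bulk_cohort <- function(signatures, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  signatures <- as.matrix(signatures)
  k <- ncol(signatures)
  if (k < 2) stop("need >= 2 signatures to form mixtures")
  if (any(signatures < 0)) stop("signatures must be non-negative")
  hazards <- rep_len(config$hazards, k)
  if (any(hazards <= 0)) stop("hazards must be > 0")
  set.seed(config$seed + 2L)
  n <- config$n_patients
  pats <- sprintf("patient%04d", seq_len(n))
  w <- matrix(rgamma(n * k, shape = config$mixture_alpha), n, k)
  # at tiny concentrations all gamma draws can underflow to zero; such a
  # patient is one-hot on a uniformly drawn signature
  bad <- rowSums(w) == 0
  if (any(bad))
    w[cbind(which(bad), sample.int(k, sum(bad), replace = TRUE))] <- 1
  w <- w / rowSums(w)
  grp <- max.col(w, ties.method = "first")
  prof <- signatures %*% t(w)
  if (config$bulk_noise_sd > 0)
    prof <- prof + matrix(rnorm(length(prof), 0,
                                config$bulk_noise_sd * mean(signatures)),
                          nrow(prof), ncol(prof))
  prof[prof < 0] <- 0
  dimnames(prof) <- list(rownames(signatures), pats)
  time <- rexp(n, rate = hazards[grp])
  event <- rep(1L, n)
  cens <- runif(n) < config$censoring_rate
  time[cens] <- runif(sum(cens), 0, time[cens])
  event[cens] <- 0L
  list(bulk = expression_matrix(prof, scale = "TPM",
                                sample_meta = data.frame(
                                  dataset = "synthetic-bulk",
                                  condition = "bulk",
                                  stringsAsFactors = FALSE)[rep(1, n), ,
                                                            drop = FALSE]),
       survival = survival_table(pats, time, event),
       truth_group = setNames(grp, pats))
}

#' Illustrative tumor-signature gene sets for a simulated dataset
#'
#' Builds the fourteen canonical tumor-state gene sets (angiogenesis,
#' apoptosis, cell cycle, differentiation, DNA damage, DNA repair, EMT,
#' hypoxia, inflammation, invasion, metastasis, proliferation, quiescence,
#' stemness) over the simulated gene universe. The stemness set is the
#' planted stemness program (genes whose expression falls along latent time)
#' and the differentiation set is the planted time program, so the stemness
#' enrichment score genuinely tracks the generator's latent axis; the other
#' twelve sets are seeded random draws from the background genes.
#'
#' @param sim a [simulate_cells()] result
#' @param set_size members per random set
#' @param seed integer seed for the random sets
#' @return named list of 14 character vectors
#' @export
simulate_gene_sets <- function(sim, set_size = 25L, seed = 1L) {
  canon <- c("angiogenesis", "apoptosis", "cell cycle", "differentiation",
             "DNA damage", "DNA repair", "EMT", "hypoxia", "inflammation",
             "invasion", "metastasis", "proliferation", "quiescence",
             "stemness")
  set.seed(seed)
  bg <- sim$genes$background
  sets <- lapply(canon, function(nm) sample(bg, min(set_size, length(bg))))
  names(sets) <- canon
  sets[["stemness"]] <- sim$genes$stemness_program
  sets[["differentiation"]] <- sim$genes$time_program
  sets
}
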