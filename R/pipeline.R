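#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end orchestration against the generator: simulate a catalog and
#' single cells (with doublet contamination per the config), filter doublets
#' (auto threshold), compute zFPKM activation, the OR repertoire profile and
#' co-expression distribution, gene-set enrichment scores (including the
#' stemness score used for rooting), the kNN-graph embedding / clusters /
#' pseudotime and its correlation table, median-split differential
#' expression, cluster-level OR signatures, a simulated bulk cohort
#' projected by cosine similarity, patient stratification, and per-group
#' Kaplan-Meier curves with a log-rank test. Given one config (and its
#' seed) the output is fully deterministic; when `out_dir` is supplied every
#' stage's table is also written as a TSV.
#'
#' @param config a [sim_config()]
#' @param out_dir optional directory for TSV outputs (created if missing)
#' @param activation_threshold zFPKM activation threshold, default -3
#' @param n_signature_clusters passed to [build_or_signatures()]
#' @param n_patient_groups passed to [stratify_patients()]
#' @return a list with the intermediate objects of every stage
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         activation_threshold = -3,
                         n_signature_clusters = "auto",
                         n_patient_groups = "auto") {
  sim <- simulate_cells(config)
  contaminated <- inject_doublets(sim$matrix, config$doublet_rate,
                                  seed = config$seed + 3L)

  dbl_report <- score_doublets(contaminated$matrix, seed = config$seed + 4L)
  called <- call_doublets(dbl_report, contaminated$matrix, threshold = "auto")
  cells_kept <- colnames(called$matrix$values)
  singlets <- subset_samples(called$matrix,
                             cells_kept %in% sim$truth$cell_id)
  truth <- sim$truth[match(colnames(singlets$values), sim$truth$cell_id), ]

  z <- zfpkm_transform(singlets)
  act <- binarize_activation(z, threshold = activation_threshold)
  orpos <- or_positive_cells(act, sim$catalog)
  profile <- or_counts_per_cell(act, sim$catalog, expression = singlets)
  coexpr <- coexpression_distribution(profile)

  sets <- simulate_gene_sets(sim, seed = config$seed)
  scores <- gsva_scores(singlets, sets)
  stemness <- scores["stemness", ]

  embed <- embed_and_cluster(singlets, seed = config$seed,
                             exclude_genes = sim$catalog$symbol)
  root <- select_root(embed, stemness)
  pt <- compute_pseudotime(embed, root$root_cell)
  pt_cor <- pseudotime_correlations(pt, stemness, profile)

  split <- median_split(profile, embed$clusters)
  labels <- split$group
  labels[split$cluster %in% attr(split, "excluded_clusters")] <- "excluded"
  de <- wilcoxon_de(singlets, labels)

  # signatures: ORs active somewhere, built from OR-positive cells only
  # (cells without any expressed OR carry no receptor co-activation signal)
  or_f <- sim$catalog$symbol[sim$catalog$status == "functional"]
  or_rows <- intersect(rownames(act), or_f)
  or_active <- or_rows[rowSums(act[or_rows, , drop = FALSE]) >= 1]
  pos_cells <- which(orpos$positive)
  or_expr <- structure(list(values = singlets$values[or_active, pos_cells,
                                                     drop = FALSE],
                            scale = "TPM", sample_meta = NULL),
                       class = "expression_matrix")
  or_act <- act[or_active, pos_cells, drop = FALSE]
  class(or_act) <- class(act)
  attr(or_act, "threshold") <- attr(act, "threshold")
  sigs <- build_or_signatures(or_expr, or_act,
                              n_clusters = n_signature_clusters)

  # bulk cohort mixed from whole-transcriptome cluster means (TPM)
  cl <- sigs$cell_cluster
  sig_tpm <- vapply(sort(unique(cl)), function(k)
    rowMeans(singlets$values[, names(cl)[cl == k], drop = FALSE]),
    numeric(nrow(singlets$values)))
  rownames(sig_tpm) <- rownames(singlets$values)
  cohort <- simulate_bulk_cohort(sig_tpm, config)
  sim_mat <- project_signatures(cohort$bulk, sigs)
  groups <- stratify_patients(sim_mat, n_groups = n_patient_groups)
  surv <- cohort$survival
  surv$group <- unname(groups[surv$patient_id])
  curves <- lapply(sort(unique(stats::na.omit(surv$group))), function(g)
    km_estimate(surv, group = g))
  names(curves) <- sort(unique(stats::na.omit(surv$group)))
  lr <- logrank_test(surv)

  result <- list(config = config, sim = sim, doublet_report = called$report,
                 singlets = singlets, truth = truth, zscores = z,
                 activation = act, or_positive = orpos, profile = profile,
                 coexpression = coexpr, gene_sets = sets, scores = scores,
                 embedding = embed, root = root, pseudotime = pt,
                 pseudotime_correlations = pt_cor, de = de,
                 signatures = sigs, cohort = cohort, similarity = sim_mat,
                 groups = groups, survival = surv, km_curves = curves,
                 logrank = lr)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' Write the pipeline's stage tables as TSVs
#'
#' Plain deterministic TSVs (no timestamps, fixed column order), so two runs
#' with the same config produce byte-identical files.
#'
#' @param result a [run_pipeline()] result
#' @param out_dir destination directory
#' @return `out_dir`, invisibly
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) write.table(df, file.path(out_dir, name),
                                      sep = "\t", quote = FALSE,
                                      row.names = FALSE)
  w(result$doublet_report, "doublet_report.tsv")
  w(data.frame(cell_id = names(result$or_positive$positive),
               or_positive = as.integer(result$or_positive$positive)),
    "or_positive_cells.tsv")
  w(result$profile, "repertoire_profile.tsv")
  w(result$coexpression$table, "coexpression_distribution.tsv")
  w(data.frame(signature = rownames(result$scores), result$scores,
               check.names = FALSE), "enrichment_scores.tsv")
  w(data.frame(cell_id = names(result$embedding$clusters),
               cluster = result$embedding$clusters,
               pseudotime = as.numeric(
                 result$pseudotime[names(result$embedding$clusters)])),
    "clusters_pseudotime.tsv")
  w(result$pseudotime_correlations, "pseudotime_correlations.tsv")
  w(as.data.frame(result$de), "differential_expression.tsv")
  w(data.frame(or_symbol = rownames(result$signatures$signatures),
               result$signatures$signatures, check.names = FALSE),
    "or_signatures.tsv")
  w(data.frame(patient_id = rownames(result$similarity), result$similarity,
               group = unname(result$groups[rownames(result$similarity)]),
               check.names = FALSE), "similarity_matrix.tsv")
  w(as.data.frame(result$survival), "survival_groups.tsv")
  km <- do.call(rbind, lapply(names(result$km_curves), function(g)
    data.frame(group = g, as.data.frame(result$km_curves[[g]]))))
  w(km, "km_curves.tsv")
  w(data.frame(chi_square = result$logrank$chi_square,
               df = result$logrank$df, p = result$logrank$p),
    "logrank_test.tsv")
  invisible(out_dir)
}
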