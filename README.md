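# orsmell

Single-cell analysis of ectopic chemosensory receptor expression in tumors:
from per-cell olfactory receptor (OR) activation calls to survival-stratified
bulk cohorts.

## The problem

Humans carry ~400 functional OR genes (plus ~600 pseudogenes). Outside the
olfactory epithelium they are mostly silent, but malignant cells activate
them ectopically, and the *repertoire* of activated receptors — how many per
cell, which ones, and how that count tracks differentiation state — is a
readout of tumor cell state with prognostic value. Bulk RNA-seq masks this
signal; single-cell data expose it. `orsmell` is for computational biologists
who want a tested, deterministic pipeline for this analysis, along with a
synthetic-data generator that makes every stage verifiable without any
external download.

## What it computes

1. **Doublet filtering** — simulated-doublet kNN scores on PCA of
   log2(TPM+1), Otsu auto-threshold.
2. **Activation calling (zFPKM)** — per cell, a half-Gaussian background fit
   of positive log2(TPM): peak `mu` from an exact kernel-density argmax,
   scale `sigma = (U - mu)·sqrt(pi/2)` from the right-tail mean, scores
   `z = (x - mu)/sigma`. A gene is active in a cell iff `z > -3` (boundary
   inactive); gene-level activity takes the median z across cells. Zero-TPM
   entries are `-Inf` sentinels, never active.
3. **Repertoire statistics** — per-cell OR counts `K`, the "one or none"
   fraction, tumor-type specificity (exclusive vs broad receptors), and a
   Shapiro–Wilk-gated count-versus-expression correlation.
4. **Gene-set enrichment** — single-sample scores from a rank-weighted
   Kolmogorov–Smirnov random walk (Gaussian kernel CDF with bandwidth
   `s_i/4`, `tau = 1`, max-diff enrichment statistic) over the fourteen
   canonical tumor-state signatures, including the stemness score.
5. **Trajectory** — PCA + mutual-kNN greedy-modularity clusters, root at the
   maximum-stemness cluster's medoid, pseudotime as the kNN-graph geodesic,
   and the correlation table (pseudotime vs stemness, OR count, OR
   expression).
6. **Differential expression** — global-median split of cells by OR count
   applied within clusters, Mann–Whitney tests (exact by enumeration for
   small groups), pseudocounted fold change with the |FC| ≥ 4, p < 0.05
   gate; one-vs-rest cluster markers.
7. **Signatures → bulk** — hierarchical clustering of binary OR profiles
   (Jaccard distance), per-cluster mean-expression signatures, cosine
   projection `cos(A,B) = Σ A_i B_i / (√Σ A_i² · √Σ B_i²)` onto bulk
   patients, hierarchical patient stratification, Kaplan–Meier curves and a
   Mantel–Cox log-rank test between groups.

The synthetic generator (`sim_config()`, `simulate_cells()`,
`inject_doublets()`, `simulate_bulk_cohort()`) plants a latent
differentiation axis, a stemness-coupled OR count
(`K ~ Poisson(lambda0 + beta·s)`), recurrent per-cluster receptor pools,
doublets, and bulk mixtures with group-dependent exponential survival — so
parameter-recovery tests have exact ground truth.

## Worked example

```r
library(orsmell)

cfg <- sim_config(seed = 7, n_cells = 300, n_background_genes = 300,
                  n_or_functional = 150, n_or_pseudo = 10,
                  or_rate_base = 1, or_stemness_slope = 4)
res <- run_pipeline(cfg)

res$or_positive$percent                 # 90.3  (% cells with >= 1 active OR)
res$coexpression$one_or_none_fraction   # 0.273 (cells breaking the OSN rule: 73%)
res$pseudotime_correlations
#>                               pair      r        p test_used
#> 1           pseudotime vs stemness -0.739 1.03e-31  spearman
#> 2           pseudotime vs or_count -0.463 1.02e-10  spearman
#> 3 pseudotime vs mean_or_expression -0.142 6.00e-02  spearman
#> 4             stemness vs or_count  0.510 4.87e-13  spearman
res$signatures$meta
#>   cluster n_cells mean_or_count
#> 1       1      49          3.47
#> 2       2      56          3.79
#> 3       3      54          2.89
res$logrank
#> chi-square = 65.29 (df 2), p = 6.64e-15
```

Read: stemness falls along pseudotime (r = −0.74) and cells lose expressed
ORs as they differentiate (r = −0.46), exactly the planted coupling
(`beta = +4` on the stemness side); the three OR signatures project onto the
simulated bulk cohort into patient groups whose survival differs strongly
(log-rank p ≈ 7e-15). With `or_stemness_slope = 0` (the "healthy" null) the
pseudotime–count correlation vanishes.

Per-stage functions (`zfpkm_transform()`, `binarize_activation()`,
`gsva_scores()`, `build_or_signatures()`, `project_signatures()`,
`stratify_patients()`, `km_estimate()`, `logrank_test()`, …) are exported
individually; `inst/scripts/orsmell.R` is a thin command-line wrapper
(`simulate`, `validate`, `activate`, `doublets`, `pipeline` subcommands).

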