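---
title: "Methods: olfactory receptor repertoire analysis from single cells to survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: olfactory receptor repertoire analysis from single cells to survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Most human olfactory receptor (OR) genes are silent outside the olfactory
epithelium, yet malignant cells ectopically activate them, and the
repertoire of activated receptors carries information about tumor cell
state. `orsmell` implements an end-to-end analysis of that repertoire from
single-cell TPM matrices: per-cell activation calling, repertoire
statistics, pathway-enrichment correlation, a differentiation trajectory,
and projection of cluster-level OR signatures onto bulk cohorts with
survival stratification. Because the interesting claims are statistical
(signs of correlations, separability of patient groups), the package ships
a generator that produces data with exactly the structure those claims
presuppose, plus matched null modes; every stage is tested against that
generator's ground truth.

## Activation calling (zFPKM)

Expression support alone ("TPM > 0") is a poor activation criterion in
scRNA-seq: the low-expression background varies per cell. We therefore fit,
per cell, a half-Gaussian to the log2 distribution of its positive TPM
values: the background peak `mu` is the argmax of an exact Gaussian-kernel
density (Silverman's rule-of-thumb bandwidth, 512 grid points spanning the
data range padded by three bandwidths), and the scale is
`sigma = (U - mu) * sqrt(pi/2)` where `U` is the mean of the values above
the peak — the mean of a half-Gaussian right tail. Scores are
`z = (x - mu)/sigma`; a gene is active in a cell when `z > -3`, with the
boundary value itself inactive, and active at the gene level when the
median of its z-scores across cells exceeds −3 strictly.

Two numerical choices matter:

* **Zeros are sentinels, not data.** Zero-TPM entries never enter the fit
  and receive `-Inf`. Including the zero spike would place the density peak
  at the spike, making every expressed gene look active. A gene expressed
  in fewer than half the cells is therefore gene-level inactive by
  construction — intended behaviour, since the median rule asks for
  majority support.
* **The density is an exact kernel sum**, not a binned FFT approximation,
  so the peak provably equals the brute-force evaluation the tests compare
  against. Cells with fewer than 50 positive entries are skipped with a
  warning (`NA` column); a cell whose positive values have no spread is a
  fit error rather than a silent zero-sigma.

The transform is fit per cell (column-wise), matching the per-sample
contract of the standard implementation; the gene-level median rule is then
applied across cells. The per-cell scale invariance (multiplying a cell's
TPM by any constant leaves z unchanged) is tested to 1e-6.

## Doublet filtering

Before any repertoire statistics, suspected doublets are removed with a
deliberately compact simulated-doublet classifier: PCA of log2(TPM+1),
synthetic doublets as random-pair TPM means projected into the same PC
space, and per cell the fraction `f` of its `k = 20` nearest neighbours
that are synthetic, mapped to a score via the class-imbalance correction
`(f/rho)/((f/rho) + 1 - f)`, `rho = sim_ratio/(1 + sim_ratio)`. There is no
variance stabilization, gene selection, or expected-rate prior; the design
target is behavioural — planted doublets in two-cluster data are recovered
at AUROC ≥ 0.9 — not score-level parity with heavier tools. Auto
thresholding uses Otsu's criterion on the score histogram; ties in
neighbour distance break by column index so results are reproducible.

## Repertoire statistics

"Expressed OR" always means an activation-matrix 1 (`z > -3`), so per-cell
OR counts, the OR-positive-cell percentage, and the co-expression
distribution share one definition. The per-cell mean OR expression averages
log2(TPM+1) over that cell's active receptors only; cells with none
contribute a structural zero and are excluded from the count–expression
correlation. Correlations package-wide use a Shapiro–Wilk gate at
`alpha = 0.05`: Pearson if both variables look normal, Spearman otherwise,
with the test recorded alongside `r` and `p`. (Shapiro–Wilk caps at 5000
observations; larger inputs are gated on a deterministic evenly spaced
subsample, while the correlation itself uses all points.)

## Gene-set enrichment

Single-sample scores use a rank-weighted Kolmogorov–Smirnov random walk:
per-gene Gaussian-kernel CDF values (bandwidth `s_i/4`, floored at 1e-8 for
constant genes), per-sample ranking by decreasing CDF with symmetric rank
centering, member steps weighted `|rank|^tau` with `tau = 1`, uniform
non-member penalty, and the `max_diff` summary (largest positive plus most
negative walk deviation). These are the published defaults of the GSVA
family of methods, adopted as-is. The fourteen canonical tumor-state
signatures (angiogenesis … stemness) are user-supplied GMT files; the
package's generator builds illustrative sets for testing, with the
stemness set tied to the planted stemness program so the stemness score
genuinely tracks the latent axis. The per-cell stemness score that roots
the trajectory is exactly the "stemness" row of this matrix. No permutation
p-values are attached to set scores; a plain threshold utility would be
possible, but classification of "activated pathways" at a corrected-p
cutoff is out of scope because the correction details are not specified by
the activation rule itself.

## Trajectory

The embedding standardizes log2(TPM+1) per gene (zero-variance genes
dropped, standardized values clipped at ±10 — the usual guard against
zero-inflated genes dominating Euclidean distances), takes 30 PCs, builds a
mutual kNN graph (`k = 15`, ties by index), and clusters it by greedy
modularity maximization; isolated vertices are tied to their single nearest
neighbour so no cell is stranded. The root cluster is the one with maximal
mean stemness (ties to the smallest id, with a warning) and the root cell
is that cluster's embedding medoid. Pseudotime is the Dijkstra geodesic
from the root on a symmetrized kNN graph with Euclidean edge weights,
rescaled to [0, 1]; cells unreachable from the root are flagged `NA`.

This is a deliberate simplification of principal-graph pseudotime methods:
the downstream claims depend only on an ordering rooted at maximal
stemness, which the geodesic provides with far less machinery. Two
analysis decisions deserve emphasis. First, chemoreceptor genes can (and in
the packaged pipeline do) get excluded from the embedding: at desk scale
receptors are a third of the simulated gene universe rather than ~2% of a
transcriptome, and letting them shape the embedding would make the
pseudotime-versus-OR-count correlation partly circular. Second, no branch
detection is attempted; the result is a single rooted ordering.

## OR signatures, projection, stratification, survival

Cells are clustered on their binary OR profiles with Jaccard distance.
Ward linkage (`ward.D2`) is the default: most pairwise Jaccard distances
between sparse receptor profiles equal exactly 1, and average linkage
chains into one giant cluster on such data, which we observed directly;
Ward on the same distances recovers planted repertoire clusters. Two empty
OR profiles are defined to be at distance 0 (the binary distance is
otherwise undefined there). Each signature is the per-gene mean log2(TPM+1)
of its member cells — expression averaging rather than binary averaging,
because cosine projection onto continuous bulk profiles needs comparable
magnitudes — annotated with member count and mean per-cell OR count.
Signature building uses OR-positive cells; cells with no expressed
receptor carry no co-activation information, and their all-zero signature
would have an undefined cosine.

Projection restricts the bulk matrix to the signature genes (missing genes
zero-filled with a warning), log2-transforms, and fills a patients ×
signatures cosine-similarity matrix; all-zero patients are flagged and
excluded. Stratification clusters the similarity rows hierarchically
(Euclidean, Ward), after two refinements that are on by default and can be
disabled: rows are centered at their means (the similarities of one patient
share a level set by overall OR content; the signal is the relative
affinity pattern), and after cutting the dendrogram patients are
iteratively reassigned to the nearest group centroid until convergence —
a deterministic cleanup of boundary patients that a single cut misplaces.
Survival per group uses the product-limit estimator and a Mantel–Cox
log-rank test (standard tie convention: censored observations at an event
time stay at risk through the event), both delegated to the `survival`
package and cross-checked in the tests against brute-force risk-set
recomputation and a hand-worked hypergeometric oracle.

## The synthetic generator

`sim_config()` fixes the study conditions; one seed determines everything.
Per cell: latent time `t ~ U(0,1)`; stemness `s = 1 - t + N(0, 0.1)`;
expressed-OR count `K ~ Poisson(max(0, lambda0 + beta*s))`; OR identities
drawn without replacement, each with probability 0.8 from the cell
cluster's 5-receptor recurrent pool and otherwise uniformly. Background
genes have log-normal expression (log2 mean 5, sd 1.5) with
expression-dependent dropout — detection probability logistic in the
latent mean (baseline 0.5, slope 1.5) — 100 program genes whose means move
±3 log2 along `t` (the down-with-`t` half is the stemness program), and 20
markers per cluster shifted +2 log2. Columns are renormalized to TPM.
Doublets are parent means renormalized (TPM is compositional, so means and
sums coincide after renormalization). Bulk patients are
Dirichlet(0.15)-weighted mixtures of cluster signatures plus truncated
Gaussian noise, with exponential survival at per-group hazards
(0.9, 0.3, 0.1) and 20% uniform censoring.

Three generator choices were made during development because without them
the planted structure is unrecoverable *in principle*, not merely
inconveniently: (i) dropout must covary with expression level, as it does
in real droplet data — mean-independent dropout buries the differentiation
axis below the PCA noise floor; (ii) receptor choice must be recurrent
within subpopulations — with fully exchangeable OR choice among hundreds
of receptors, two cells almost never share a receptor, every pairwise
Jaccard distance is 1, and receptor-profile clustering is structureless,
whereas recurrently activated receptors are exactly what tumor data show;
(iii) bulk patients must be clearly dominated by one subclone signature
(small Dirichlet concentration) for "groups with distinct survival" to be a
well-posed target. The generator does not attempt UMI count noise,
library-size variation, batch effects, or platform differences — so
passing tests demonstrate correct recovery of the modelled structure, not
robustness to real-data artefacts.

## Problem sizes and defaults

Tests and the acceptance script run at desk scale, chosen so the whole
suite completes in minutes on one core while leaving the statistical
targets comfortably powered: single-cell simulations of 150–1000 cells
over 300–460 genes (150–400 of them ORs), 50-replicate trajectory
sign-recovery runs, 100-replicate cohort stratification runs with 200
patients each, and 200-replicate type-I-error checks. Defaults that matter:
activation threshold −3 (strict), `min_positive = 50` per cell,
`n_pcs = 30`, `k_nn = 15`, doublet `k = 20`, `sim_ratio = 1`, DE gates
|FC| ≥ 4 (pseudocounted linear fold change, `(mean+1)/(mean+1)`) with raw
`p < 0.05` per the median-split design, marker gates FC ≥ 2. Fold change is
linear with pseudocount 1 — the conventional reading when no formula is
stated — and a log2 column plus a Benjamini–Hochberg column are reported
without being gated on.

## Known limitations

* Pseudotime is a geodesic ordering, not a principal graph; branching
  topologies collapse onto one ordering.
* The normality-gated correlation is an interpretation of a tersely stated
  testing rule ("Shapiro–Wilk for correlation"); it is applied uniformly
  and always reported with the chosen test.
* Gene identity is by case-sensitive symbol; no alias or cross-reference
  resolution.
* Enrichment p-values for set scores are not computed; scores are used for
  ranking, rooting and correlation only.
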