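# cafscape

Statistical toolkit for pan-cancer spatial single-cell analyses of
cancer-associated fibroblasts (CAFs) — and, more generally, for any study
that asks *which cell types live near which*, *which regulons and gene
programs mark a subpopulation*, and *how reproducible those answers are
across tissue sections and cohorts*.

Once single cells have been charted onto tissue coordinates (e.g. by a
CellTrek-style coordinate transfer) and regulon activities scored (e.g. by
AUCell), the remaining statistics are simple but easy to get subtly wrong:
per-slice neighborhood distances, consensus rankings across slices,
divergence-based specificity scores, running-sum gene-set scores,
information-theoretic homogeneity, and contingency-table preferences.
`cafscape` implements exactly that layer, with a synthetic-data module that
plants known structure so every stage can be validated against ground truth.

## What it computes

- **Spatial k-distance** (`k_distance`): for each cell, the mean Euclidean
  distance to its k nearest cells of a reference type within the same
  slice (k = 10 by default, self excluded, exact all-pairs search).
- **Per-slice proximity rankings and consensus** (`celltype_proximity_ranking`,
  `rra`): cell types sorted from closest to farthest per slice, then
  integrated by robust rank aggregation. For an item with sorted normalized
  ranks r(1) ≤ … ≤ r(n) across n lists,
  β\_k = P(U\_(k) ≤ r(k)) for the k-th uniform order statistic,
  ρ = min\_k β\_k, and p = min(1, n·ρ).
- **Proximal/distal enrichment** (`proximal_partition`,
  `proximity_enrichment`): the 10% of cells closest to the reference type
  form the proximal region per slice; per-type proportion differences
  between regions are tested with paired t-tests across slices.
- **Regulon specificity score** (`rss`, `rss_matrix`):
  RSS(R, C) = 1 − √JSD(P^R, P^C), with P^R the activity distribution over
  cells, P^C the normalized cell-type indicator, and JSD the base-2
  Jensen–Shannon divergence; top-5 regulons flagged per type.
- **Signature scores** (`ssgsea_score`, `aucell_score`,
  `geometric_mean_score`, `mean_score`, `weighted_sum_score`,
  `median_split`, `icaf_score_pipeline`): the single-sample GSEA running
  sum (α = 0.25), AUCell-style recovery-curve AUC, the geometric-mean
  cytolytic score (CYT = √(GZMA·PRF1)), mean-expression scores (TLS, IFN-γ,
  expanded immune), the housekeeping-normalized weighted T-cell-inflamed
  sum, and median-based high/low splitting.
- **Transcriptional homogeneity** (`discretize`, `pairwise_nmi`,
  `homogeneity`): per-gene 10-bin discretization, pairwise normalized
  mutual information NMI = I(X;Y)/√(H(X)H(Y)), subsampled 100 cells × 100
  replicates per sample.
- **Cancer preference** (`preference_or`): per (subtype, cancer) 2×2
  tables, cross-product odds ratios (Haldane +0.5 when a cell is zero) and
  two-sided Fisher exact p-values.
- **Core I/O and QC** (`read_cell_map`, `read_expression`, `read_gmt`,
  `qc_filter`, `find_markers`): CSV/TSV cell maps, Matrix Market or dense
  CSV expression, GMT gene sets, droplet QC (≤40,000 UMIs, 500–5,000
  genes, ≤20% mitochondrial), and a one-vs-rest Wilcoxon marker finder
  (|log2FC| > 1, BH-adjusted p < 0.05).
- **Synthetic data** (`simulate_collection`, `simulate_regulon_activity`,
  `simulate_ranked_lists`, `simulate_bulk_cohort`): multi-slice spatial
  maps with configurable attraction/repulsion, negative-binomial
  expression with planted markers, regulon matrices with planted targets,
  ranked lists with planted consensus items, and bulk cohorts with a
  planted group effect.

## Worked example

Simulate six tissue slices in which endothelial cells are attracted to
iCAFs and epithelial cells are repelled, then ask the package to find that
structure:

```r
library(cafscape)

cfg <- simulation_config(
  n_slices = 6, cells_per_slice = 300, seed = 7,
  cell_types = c(iCAF = 0.3, mCAF = 0.2, Endothelial = 0.25, Epithelial = 0.25),
  spatial_rules = list(
    spatial_rule("Endothelial", "iCAF", "attract", strength = 0.9, range = 10),
    spatial_rule("Epithelial",  "iCAF", "repel",   strength = 4,   range = 30)))
sim <- simulate_collection(cfg)

rl <- celltype_proximity_ranking(sim$cells, ref_type = "iCAF", k = 10)
rra(rl)
#>          item         rho p_corrected consensus_rank
#> 1 Endothelial 0.001371742 0.008230453              1
#> 2        mCAF 0.087791495 0.526748971              2
#> 3  Epithelial 1.000000000 1.000000000              3

proximity_enrichment(sim$cells, "iCAF", k = 10, fraction = 0.10)
#>     cell_type n_slices  mean_diff         t            p         direction
#> 1 Endothelial        6  0.7044973  95.27023 2.415490e-09 proximal-enriched
#> 2  Epithelial        6 -0.3715068 -42.84741 1.306622e-07   distal-enriched
#> 3        mCAF        6 -0.3329905 -90.76740 3.076732e-09   distal-enriched
```

The attracted type tops the consensus proximity ranking (ρ small, corrected
p < 0.05) and is significantly enriched in the iCAF-proximal region, while
the repelled type is pushed to the distal region — the planted geometry,
recovered. The same pattern applies to real data: feed `read_cell_map()` a
CSV of charted cells and the calls above are unchanged.

Regulon specificity works the same way against planted regulon targets:

```r
reg <- simulate_regulon_activity(8, c("iCAF", "mCAF"), cells_per_type = 60,
                                 specificity = 0.9, seed = 7)
rs <- rss_matrix(reg$ras)
head(rs[order(-rs$rss), ], 4)
#>      regulon cell_type       rss rank_in_type  top
#> 14 REG006(+)      mCAF 0.9080837            1 TRUE
#> 1  REG001(+)      iCAF 0.9010809            1 TRUE
#> 7  REG007(+)      iCAF 0.8981227            2 TRUE
#> 3  REG003(+)      iCAF 0.8948328            3 TRUE
```

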