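---
title: "Methods and design notes for cafscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for cafscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafscape)
```

`cafscape` implements the statistical layer that sits between upstream
single-cell tooling (coordinate transfer of scRNA-seq cells onto spatial
transcriptomics sections, regulon scoring, clustering) and biological
conclusions about cancer-associated fibroblasts (CAFs) and their
microenvironment. This vignette documents each statistic, the assumptions
behind it, the conventions chosen where the underlying methods literature
leaves choices open, and what the synthetic test bed does and does not
establish.

## Spatial k-distance and proximity analysis

For a cell $i$ in slice $s$ and a reference cell type $R$, the spatial
k-distance is the arithmetic mean of the Euclidean distances from $i$ to
its $k$ nearest cells of type $R$ in the same slice. Distances are
computed in the slice's native coordinate units — no harmonization across
slices is attempted, which is why all downstream aggregation is rank- or
proportion-based. The default $k = 10$ is the conventional neighborhood
size for this statistic.

Conventions worth knowing:

* **Self-exclusion.** A reference-type cell never counts itself among its
  $k$ nearest reference cells: a self-distance of zero would make the
  statistic degenerate for every reference cell. Consequently a slice
  needs at least $k$ reference cells for non-reference queries and $k + 1$
  for reference-type queries; slices below the floor are skipped with a
  warning and flagged in the result.
* **Determinism under ties.** Ties at the $k$-th neighbor are broken by
  reference cell id in lexicographic order, and ties in every ranking or
  partition below are broken by name/id as well, so all outputs are exact
  functions of their inputs.
* **Exact search.** Neighbors are found by exact all-pairs evaluation.
  At the slice sizes this statistic is used at (hundreds to a few thousand
  cells) the quadratic scan is fast, and exactness lets tests compare
  against an independent brute-force oracle with zero tolerance.

**Proximity ranking.** Per slice, non-reference cell types are ordered by
the mean k-distance of their member cells, closest first. Types absent
from a slice are simply missing from that slice's list (partial lists are
handled by the rank aggregation below).

**Proximal/distal partition.** Within each slice the
$\max(1, \lfloor f \cdot n \rfloor)$ eligible cells with the smallest
k-distance form the reference-proximal region ($f = 0.10$ by default,
i.e. the 10% of cells *nearest* the reference type); the rest are distal.
Two deliberate choices: the partition is computed per slice, never pooled
(slices differ in scale and cell counts), and reference-type cells are
excluded from eligibility and from the region proportions — they would
trivially dominate the proximal decile and drown the signal of every other
type. Whether to include them is genuinely open; exclusion is this
package's documented convention.

**Enrichment testing.** For each cell type, the per-slice difference
between its proximal and distal proportions is tested with a paired
t-test across slices ($t = \bar d / (s_d/\sqrt m)$, $df = m - 1$,
two-sided). Types contributing fewer than two slices are dropped with a
warning. If the differences are constant and nonzero ($s_d = 0$) the type
is reported with $p = 0$ and a `degenerate` flag rather than an error —
such rows deserve a human look, not silent removal. The paired t assumes
approximately normal per-slice differences; with few slices the test is
only approximate, which the null-calibration check below quantifies.

## Robust rank aggregation

Given $n$ ranked lists over a universe of $N$ items, each item's positions
are normalized to $r = \text{position}/N \in (0, 1]$; items missing from a
list are imputed at $r = 1$ (ranked last — conservative, since a missing
item can only look less of a consensus hit). With the item's sorted
normalized ranks $r_{(1)} \le \dots \le r_{(n)}$, the beta score

$$\beta_k = P\big(U_{(k)} \le r_{(k)}\big)
  = \sum_{l=k}^{n} \binom{n}{l} r_{(k)}^l (1 - r_{(k)})^{n-l}$$

is the probability that the $k$-th order statistic of $n$ iid
Uniform$(0,1)$ draws lies at or below the observed value; it is evaluated
through the regularized incomplete beta function (`pbeta(r, k, n-k+1)`),
which is numerically stable where the binomial sum loses digits. The
aggregation score is $\rho = \min_k \beta_k$ and the corrected p-value
applies a Bonferroni factor for the $n$ minima considered:
$p = \min(1, n\rho)$. Because each $\beta_k$ is marginally uniform under
the null, the true tail probability of the minimum is bracketed between
$\rho$ and $n\rho$; the test suite verifies this bracket against a
100,000-draw Monte-Carlo null and checks that the corrected p's empirical
type-I error stays at or below the nominal level.

`aggregate_lri()` applies the same machinery to per-slice
ligand–receptor interaction counts: pairs are ranked by descending
occurrence frequency within each slice (ties by pair name) over the union
universe, then aggregated.

## Regulon specificity score

For a regulon with activity vector $a$ over $n$ cells and a cell type
covering a subset $C$, the score is

$$\mathrm{RSS}(R, C) = 1 - \sqrt{\mathrm{JSD}(P^R, P^C)}, \qquad
  \mathrm{JSD}(p, q) = H\!\left(\tfrac{p+q}{2}\right)
   - \tfrac{H(p) + H(q)}{2},$$

where $P^R = a / \sum_i a_i$, $P^C$ is the normalized membership
indicator, and $H$ is Shannon entropy. Two conventions are fixed here:
entropy carries its standard minus sign, $H(p) = -\sum p_i \log p_i$
(without it the divergence would be negative and the square root
undefined), and logarithms are base 2, so JSD ranges over $[0, 1]$ and
disjoint supports give RSS exactly 0 while a perfectly matched uniform
activity gives exactly 1. All-zero activity vectors are excluded with a
warning rather than forced through a $0/0$ convention. The membership
distribution is computed over all analyzed cells, not per sample.

## Signature scoring

* **ssGSEA** ranks a sample's genes by expression (highest gets rank $N$;
  expression ties broken by gene name), then walks down the ranking
  accumulating an in-set fraction weighted by $|\text{rank}|^\alpha$
  (normalized by the set's total weight) against a uniform out-of-set
  fraction; the score is the *sum* of the running differences. The
  exponent defaults to $\alpha = 0.25$ and no cohort-wide min–max
  rescaling is applied. The single-sample GSEA literature varies on both
  points; the sum statistic with $\alpha = 0.25$ is the common default
  and is frozen here so results are exactly reproducible. Scores are
  rank-based and hence invariant to any strictly monotone per-sample
  transform, but comparable only within one matrix.
* **AUCell-style score**: genes ranked per cell (ties broken by a seeded
  random shuffle), recovery curve = cumulative set-gene count over the
  top $T = \lceil 0.05 N \rceil$ ranks, score = area under the step curve
  divided by the maximal area. The 5% threshold is the referenced
  method's default.
* **Geometric mean** (CYT and similar): $\exp(\mathrm{mean}(\log(x +
  \varepsilon)))$ with $\varepsilon = 0.01$ guarding against zeros; the
  offset is deliberately not subtracted afterwards, and with
  $\varepsilon = 0$ on positive data the score is the classical geometric
  mean.
* **Weighted sum** (T-cell-inflamed): signature-gene expression is
  centred per sample by the mean of user-supplied housekeeping genes,
  then combined with the published per-gene weights, which the caller
  must provide.
* **Median split** assigns scores strictly above the median to "high";
  ties at the median go to "low". The direction of the tie rule is
  arbitrary; it is fixed and documented for determinism. An all-equal
  score vector is refused as a degenerate split.

Gene symbols are matched case-insensitively after upper-casing, and
missing genes are reported by name rather than silently dropped.

## Transcriptional homogeneity

Expression of the chosen marker genes is discretized per gene into 10
equal-width bins over the analyzed population's $[\min, \max]$
(equal-frequency binning is available behind a flag; the equal-width rule
is the simplest reproducible reading of "10 bins"). Constant genes get
bin 0 everywhere, and the maximum clamps into the last bin. For two
cells, the gene-wise bin pairs define a joint distribution whose mutual
information, normalized as $I/\sqrt{H(X)H(Y)}$ (base 2 throughout —
the base cancels in the ratio but fixes intermediate values), measures
profile similarity; a constant profile ($H = 0$) is assigned NMI 0, since
it carries no shared information. Per sample, 100 cells are subsampled
100 times and the median pairwise NMI recorded per replicate; samples
smaller than the subsample contribute all their cells rather than being
dropped, and per-(sample, replicate) seeded substreams make the result
independent of sample order. Note that plug-in MI estimates are biased
upward at small gene counts, so NMI values should be compared between
populations discretized over the same genes, not read as absolute
quantities.

## Cancer-preference odds ratios

For subtype $i$ and cancer $j$ the 2×2 table counts (subtype-$i$ cells in
cancer $j$; subtype-$i$ elsewhere; non-$i$ in $j$; non-$i$ elsewhere).
The reported OR is the sample cross-product ratio $(ad)/(bc)$ — not the
conditional MLE that `fisher.test()` estimates — with the
Haldane–Anscombe $+0.5$ applied to all four cells only when some cell is
zero. The two-sided p-value is the standard Fisher exact sum of
hypergeometric probabilities at or below the observed table's, verified
in the tests against exhaustive enumeration for small margins.

## Quality control and marker finding

QC follows the droplet-data convention: cells with more than 40,000 UMIs,
fewer than 500 or more than 5,000 detected genes, or more than 20%
mitochondrial counts (symbols prefixed `MT-`, case-insensitive, the
human-genome convention) are excluded. The thresholds are strict
inequalities, so a cell exactly at a boundary is retained, and each
removed cell is annotated with the first criterion it failed in the fixed
order (umi, min_genes, max_genes, mito).

Marker detection is a one-vs-rest two-sided Wilcoxon rank-sum test per
gene per group with Benjamini–Hochberg adjustment across genes within
each group; a marker is significant at |log2FC| > 1 and adjusted
p < 0.05. The fold change is computed directly as the difference of mean
log-expression (group minus rest) — conventions differ across toolkits
(some exponentiate back to the natural scale first); the direct
difference is the simplest defensible choice and is frozen so tests are
deterministic. The rank-sum p is exact when both sides are small and the
data are tie-free, and uses the normal approximation with tie correction
otherwise, mirroring standard marker finders.

## The synthetic test bed

The generators plant known structure at single-cell resolution:

* **Spatial maps** (`simulate_collection`): anchor types follow a
  Thomas-style cluster process (Poisson number of cluster centers, at
  least one, uniform on the field; cells scattered around a uniformly
  chosen center with isotropic Gaussian dispersion at 5% of the field
  side) — emulating the dense cell-type patches visible in real sections.
  A type with an *attract* rule places each cell, with probability equal
  to the rule's strength, at a Gaussian offset (sd = `range`) from a
  uniformly chosen target cell, otherwise uniformly; *repel* rejection
  samples uniform candidates with acceptance probability
  $(1 - e^{-d/5\,\mathrm{range}})^{\mathrm{strength}}$ increasing in the
  distance $d$ to the nearest target cell (strength 0 reduces to uniform,
  matching attract at strength 0); *neutral* is uniform. Defaults — 10
  slices, 400 cells per slice, a 1000×1000 field, four cell types at
  equal abundance — are sized so per-slice type counts resemble a
  moderately sampled tissue section while keeping a full collection cheap
  to regenerate.
* **Expression**: negative-binomial counts with shared dispersion
  (size = 2) and baseline mean 5 per gene; each type's 10 planted marker
  genes have their mean multiplied by $2^{2} = 4$ in that type. These are
  generic droplet-like magnitudes: a clear but not trivial marker signal
  over substantial overdispersion.
* **Regulon matrices**: round-robin target assignment; Beta-distributed
  activity (concentration 10) with mean `specificity` on target cells and
  $(1-\text{specificity}) \cdot 0.2$ elsewhere; means are clamped away
  from {0, 1} by $10^{-6}$ so full specificity yields near-zero (not
  degenerate) off-target draws.
* **Ranked lists**: a planted item of strength $s$ draws its position
  uniformly from the first $\max(1, \lceil (1-s) N \rceil)$ slots of each
  list, so strength 1 pins it at rank 1 and strength 0 is uniform.
* **Bulk cohorts**: log-normal expression (log-scale mean 3, sd 1) with
  signature genes multiplied by $2^{\text{effect}}$ in the "high" half of
  the samples.

All generators are pure functions of (configuration, seed); the spatial
generator derives one substream per slice from the master seed, so adding
slices never perturbs earlier ones.

What the test bed does *not* emulate: tissue histology and anisotropic
structures (vessels, crypts), coordinate-transfer error and the spot
deconvolution upstream of real cell charting, gene–gene correlation
modules, batch effects, doublets, and per-gene dispersion variation.
Passing the planted-recovery tests therefore demonstrates that the
statistics are implemented correctly and are well calibrated under their
own assumptions — not that those assumptions hold in any particular
tissue.

## Validation strategy and problem sizes

The test suite works at three levels: closed forms asserted to 1e-12
(entropy, JSD, RSS, NMI, geometric means, beta scores), independent
oracles (brute-force all-pairs k-distance at zero tolerance on 500-cell
maps; binomial-sum beta scores to 1e-10 up to n = 25; exhaustive
hypergeometric enumeration of Fisher p; step-by-step re-evaluations of the
ssGSEA and AUCell curves on 10-gene fixtures), and statistical properties
(type-I error of the RRA corrected p over 2,000 null items and of the
paired t over 200 null collections, bounded by $\alpha + 2\,\mathrm{SE}$;
planted-structure recovery for attraction/repulsion across 10 slices,
consensus items over 100 seeds, regulon targets at full specificity, and
the marker→ssGSEA→median-split pipeline at 100 bulk samples). These sizes
were chosen as the smallest at which the corresponding asymptotics are
comfortably visible; `scripts/acceptance.R` re-runs the same battery from
scratch with all randomness derived from a single `--seed`.

## Known limitations

* The paired t-test on per-slice proportion differences is approximate
  for small slice counts and compositional data; with very few slices
  prefer the degenerate/constant-difference flags and the RRA consensus
  over raw p-values.
* Plug-in NMI is upward-biased for short profiles; compare populations,
  do not interpret absolute values.
* ssGSEA scores are not normalized across cohorts; median splits should
  be computed within the cohort being analyzed.
* The exact ssGSEA variant, the AUCell threshold, the log2FC convention,
  the proximal-region eligibility rule, and the median tie rule are
  documented package conventions: alternatives exist in the literature,
  and results are exactly reproducible only under the conventions stated
  here.
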