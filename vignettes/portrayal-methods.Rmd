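---
title: "Methods: SOM expression portrayal of single-cell transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM expression portrayal of single-cell transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somcell)
```

# The model

`somcell` analyses a gene-by-cell expression matrix (FPKM scale) by
*expression portrayal*: genes — not cells — are the items mapped. Each
gene's expression profile across the $n$ cells is a point in
$\mathbb{R}^n$, and a self-organizing map (SOM) condenses the roughly
$10^4$ gene profiles into a much smaller set of *metagenes* arranged on
a quadratic grid (2,500 metagenes on the default $50\times50$ grid).
Because the map is topology-preserving, co-regulated genes land on
neighbouring units, and each cell's component of every metagene — its
*portrait* — is a smooth two-dimensional landscape in which co-regulated
modules appear as contiguous over-expression *spots*.

Everything downstream operates on this representation:

* **Spots.** A summary map takes, per unit, an upper quantile (default
  0.98) of the metagene's value across cells, so modules over-expressed
  in even a small subpopulation remain visible. Units above a foreground
  quantile are segmented into spot modules; member genes are the genes
  whose best-matching unit lies in the spot, ranked by decreasing
  Pearson correlation with the spot's mean per-cell profile.
* **Groups.** Cells are compared by the Pearson correlation of their
  flattened portraits; average-linkage hierarchical clustering on
  $d = 1 - r$ with silhouette-selected $k$ yields the cell groups,
  numbered by decreasing size.
* **Gene sets.** Spot gene lists are annotated by the right-tail
  hypergeometric (Fisher) test on the universe of genes surviving
  preprocessing, reported at the conventional $p < 10^{-7}$ threshold;
  per-cell activity of a gene set is summarised by a variance-shrunken
  gene set Z-score (GSZ).
* **CNV.** Large-scale copy-number signal is inferred by averaging
  centered $\log_2$ expression over 50 consecutive genes along each
  chromosome, with per-cell median re-centering.

# Preprocessing

Cells are retained if they express (strictly $> 0$ FPKM) at least one of
the housekeeping genes ACTB and GAPDH; chambers expressing neither are
capture failures. Expression is then $\log_{10}(x+1)$-transformed,
quantile-normalized across cells (ties receive the mean of the
rank-means over their tied positions), and gene-centered
("centralized"). Whether to log-transform before quantile normalization
is genuinely open; we transform first because the raw FPKM dynamic range
otherwise lets a handful of extreme values dominate both the rank-mean
reference and SOM training. The flag `log_transform` restores the
untransformed pipeline. Zero-variance genes are dropped before training
(`min_sd = 0`), since constant rows carry no information and distort the
best-matching-unit search.

# Map training

Training is *batch* SOM: each epoch assigns every gene to its Euclidean
best-matching unit and then recomputes all units as Gaussian-weighted
means, with the neighbourhood radius decaying linearly from
$\max(\text{rows},\text{cols})/2$ to 1 over the epochs (default 30 —
enough for convergence at these problem sizes; the quantization error is
recorded in the model). Unit vectors are initialised on the plane
spanned by the first two principal components of the gene cloud, with
the sign convention that each component's largest-magnitude loading is
positive. Two consequences matter:

* **Determinism.** Batch updates remove gene-order dependence, and the
  linear initialisation is deterministic up to the fixed sign
  convention, so one seed reproduces the codebook bit for bit.
  Best-matching-unit ties break to the lowest unit index.
* **Smoothness is monotone *from above*, not from below.** The linear
  initialisation starts maximally smooth; the shrinking radius then
  trades a little smoothness for quantization accuracy. The classical
  picture of topographic order emerging gradually applies to random
  initialisation only. The property suite therefore asserts smoothness
  against a chance baseline (the mean grid distance between each gene's
  unit and its most-correlated partner's unit stays far below random
  scatter throughout training) rather than as a monotone decrease.

Empty units are legal and keep their codebook vector, so portraits are
defined everywhere on the grid. When the grid is not specified the
pipeline sizes it to roughly five genes per metagene, capped at the
$50 \times 50$ default (about 15,000 genes); the bundled preset analyses
use $25 \times 25$ for their 2,000-gene matrices.

# Spot segmentation

Foreground units are those at or above the `threshold_quantile` of the
summary map. Two segmentation methods are provided:

* `components` (default): 8-connected components of the foreground.
  4-connectivity splits diagonal ridges artificially, hence 8.
* `watershed`: each foreground component is further divided into the
  catchment basins of its local maxima, flooding in decreasing value
  order; a basin whose peak rises less than `tolerance` above the saddle
  to a higher neighbour is merged into it (prominence criterion).

The watershed mode exists because adjacent modules that share carrier
cells — an energy-metabolism module active in two groups next to a
pigmentation module, say — form one connected plateau whose interior
never dips below any sensible global threshold; only the prominence of
their separate peaks distinguishes them. Components remain the default
because they are the simpler, assumption-free reading of "contiguous
over-expressed region".

A second refinement, `refine_spots()`, addresses the converse artifact:
two genuinely unrelated *small* modules can land on adjacent or shared
units, because a map with a few hundred units cannot reserve distinct
territory for every 20-gene module. A spot whose member genes split
into two essentially uncorrelated blocks (average-linkage 2-cut with
mean between-block correlation under 0.15, both blocks at least 6
genes) is divided gene-wise. A coherent module never satisfies the
condition, since any 2-partition of co-regulated genes keeps high
between-block correlation.

The preset analyses run the summary quantile at 0.98, foreground
quantile at 0.70, watershed tolerance at 0.03 (log10 expression units),
minimum spot size at 5 units, and refinement on. These constants were
fixed once on the wild type preset across ten generator seeds so that
the planted module architecture (four major modules plus two rare ones)
emerges reliably, and are all exposed in `run_config()`. Spots with at
least 50 member genes are reported as *major* modules; the rare
subpopulation modules sit well below, the group-defining programs well
above that line.

# Group discovery

The clustering algorithm is deliberately boring: average-linkage
hierarchical clustering on the portrait correlation distance, with $k$
chosen in 2–8 by maximising the overall mean silhouette width. It is
deterministic, order-invariant up to label permutation, and every step
is checkable against a brute-force oracle. Complete linkage is available
via `linkage`. The similarity network (`edge_threshold = 0.3`) is purely
presentational; group assignment never depends on it. If all portraits
coincide, the grouping degrades to a single group with silhouette widths
reported as 0.

# Gene set statistics

The enrichment test is the standard one-sided over-representation
Fisher test, $P(X \ge a)$, with the odds ratio continuity-corrected by
0.5 when any table cell is empty. The universe is the set of genes
surviving preprocessing — not the genome — because spot membership is
defined on exactly that set. Raw p-values are reported and filtered at
$10^{-7}$ by default; a Benjamini–Hochberg column is optional.

The GSZ implemented here is a variance-shrunken standardized set sum:
for a set $S$ of $n$ genes present in the matrix and cell $c$,

$$\mathrm{GSZ}_c \;=\; \frac{\sum_{g \in S} e_{gc}}
{\sqrt{\,n\,\tilde\sigma_c^2\,}},\qquad
\tilde\sigma_c^2 \;=\; \frac{n\,\mathrm{Var}_g(e_{\cdot c})
 + \lambda\,\mathrm{Var}_{\text{global}}}{n + \lambda},$$

with $\lambda$ (`lambda_shrink`, default 10) pulling the per-cell
variance toward the global variance so small sets do not inherit an
unstable denominator. This is our formulation of the per-sample set
Z-score idea; implementations differ in their weighting constants and
we do not claim identity with any particular one.

Rare subpopulations are flagged from a GSZ profile by a largest-gap
rule: the biggest jump between consecutive sorted scores, searched where
between 1% and 50% of cells would flag, becomes the threshold — provided
the jump exceeds 2 median absolute deviations of the scores; otherwise
the profile is treated as unimodal and nothing is flagged. A quantile
threshold would be circular here (it would "find" a subpopulation of
whatever size the quantile implies); the gap rule only fires on genuine
bimodality.

# CNV inference

The signal chain is $\log_2(\mathrm{FPKM}+1)$, per-gene centering across
cells, clipping to $\pm3$, ordering by (chromosome, start), a 50-gene
moving average within each chromosome (sliding by default; block mode
for compact heatmaps), and per-cell median re-centering. Windows never
span chromosomes. Log transform, clipping and median re-centering
follow common single-cell CNV-from-expression practice and are
config-exposed; the 50-gene window is the method's defining constant.

Two limitations are structural. First, there is no reference-cell
subtraction: tumour short-term cultures contain no normal cells to use
as a baseline, so the per-cell median plays that role. Second — a
direct corollary — an event carried by essentially *all* cells is
invisible, because per-gene centering across cells removes it exactly.
The mutant-culture preset therefore plants its gains subclonally
(60% carrier fraction); this is what the procedure can in principle
see, and it mirrors the heterogeneity of real cultures.

# The synthetic-data generator

The generator is the test bed for every stage, and its defaults are the
study conditions: 2,000 genes (scalable to the full ~15,000) by 96
chambers, of which 4 fail QC, leaving 92 analysed cells. The expression
model is
$e_{gc} = \exp(\mu_g + \text{shifts}_{gc} + \varepsilon_{gc})\cdot l_c$
with per-gene baselines $\mu_g \sim N(-1, 2)$ (natural log), noise
$\varepsilon \sim N(0, 0.8)$, log-normal library factors
($\sigma = 0.3$), and expression-dependent dropout
$p = 0.9/(1+e)$ — chosen so roughly 40% of genes are detected per
cell, the detection rate typical of microfluidic single-cell FPKM
data. Planted program markers draw their baselines from a half-normal
$0.5 + |N(0,1)|$: a signature gene that is almost never captured could
not have been identified as a marker in the first place. Housekeepers
sit at a fixed high baseline (FPKM ≈ 500) so the QC filter measures
chamber failure, not dropout luck.

The wild type preset plants three major cell groups — proliferation
(45% of retained cells), a mixed group (28%), stroma (27%) — plus an
ABC/ALDH-like rare population (10%, 16 + 8 marker genes) and a
KDM5B-like one (7%). The mixed group's composition is not pinned down
by the observations the preset emulates; we resolve it by splitting its
cells into an oxphos-dominant and a pigmentation-dominant half with 0.6
cross-activation. This choice is forced in one direction and motivated
in the other: two programs with *identical* carrier cells are
statistically indistinguishable and could never form separate spots,
while real tumour subgroups do show exactly this kind of graded
fine structure. Ground truth carries both the program-level and the
merged three-group labels. Program effects default to 2.0 natural-log
units — large enough for reliable recovery, small enough that
silhouette-based model selection is not trivial.

Gene-to-chromosome placement, program membership and baselines are
drawn under a separate `layout_seed` shared across presets, with
program slices keyed canonically by name, so "proliferation" is the
same 150 genes in every culture — a prerequisite for the comparative
multi-culture analysis, where the shared proliferation signature must
actually be shared. The mutant presets (58 and 81 chambers; 54 and 77
retained) plant proliferative fractions of 30% and 36%, a dominant
culture-specific program, ABC/ALDH at 30%, and, for the BRAF-mutant
culture, single-copy gains (log2 shift 1.0) on chromosomes 11, 8, 5 and
19 in 60% of cells.

What the generator does *not* emulate: transcript-length effects in
FPKM, doublets, batch structure between replicates, ambient
contamination, and any read-level process. Passing recovery tests on
these fixtures therefore demonstrates that the pipeline's inference
machinery is correct and well-calibrated for cleanly planted structure;
it does not certify performance on real data with those additional
artifacts.

# Problem sizes and runtime

All bundled analyses and tests run at the 2,000-gene scale with 25×25
maps, where a full pipeline run takes a few seconds; the ten-seed
recovery studies complete in about a minute. The default 50×50 grid
with ~15,000 genes trains in minutes and is exercised structurally
(grid constants, warnings) rather than end-to-end in the test suite.

# Known limitations

* Spot thresholds are calibrated for the preset scale; other data sizes
  may need a different foreground quantile (all constants are exposed).
* The GSZ variant is an approximation of the cited family of set
  Z-scores, not a reimplementation of any specific one.
* Rare modules at the edge of resolvability (a couple dozen genes in
  under 10% of cells) can occasionally split across map regions or
  fail the bimodality gate; the recovery studies quantify how often.
* CNV inference reports relative, smoothed signal only — no discrete
  copy-number calls, no ploidy, no allele specificity.
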