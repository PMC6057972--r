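---
title: "Models and methods behind tmetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tmetools implements the computational analyses used to characterize an
immune tumor microenvironment under interferon-alpha gene therapy: TCR-beta
repertoire statistics, a single-cell RNA-seq pipeline from raw UMI counts
to annotated clusters and centroid trajectories, and bulk RNA-seq
preprocessing filters. This vignette records the models, the parameters
that matter, the numerical choices, and the places where the design was
genuinely open.

## Repertoire statistics

A repertoire sample is a vector of counts over unique CDR amino-acid
templates. Two statistics are computed.

**Clonality** is one minus Pielou's evenness, $C = 1 - H'/H$ with
$H' = -\sum_i p_i \ln p_i$ over templates with count $> 0$ and
$H = \ln S$ the maximal entropy for $S$ observed templates. $C$ is a pure
number in $[0, 1]$, invariant under rescaling of the counts (so raw
template counts and cpm give identical values), $0$ exactly for a uniform
repertoire and $\to 1$ as one clone dominates. Numerics: the uniform case
is detected and returned as exactly $0$ (naive summation leaves a
$\sim 10^{-16}$ residue); the monoclonal case $S = 1$ makes the ratio
$0/0$ and is *defined* as $C = 1$ with a warning, which is the limit of
$1 - H'/H$ as the distribution concentrates — the natural reading of a
repertoire collapsed to a single clone.

**Similarity** of a sample $s$ to its cohort at timepoint $t$ is one
minus the Bray–Curtis distance to the mean abundance vector
$\bar{s}_{t}$, evaluated on the union of all templates observed in the
cohort at $t$. On binarized vectors this reduces to the Sørensen–Dice
index (a property the tests verify against an independent ecology
implementation). Two open choices are resolved as follows:

* abundances are cpm-scaled before averaging — the mean of raw counts
  would be dominated by deeper-sequenced samples;
* the focal sample is *included* in the timepoint mean (the definition
  of a cohort mean carries no exclusion clause); a leave-one-out mode
  (`include_self = FALSE`) is provided for sensitivity analysis.

Adding a template absent from both the sample and the mean changes
nothing; disjoint supports give similarity $0$; equality with the mean
gives $1$.

## Single-cell pipeline

**QC.** Cells expressing fewer than 300 unique genes are discarded
(strict: a 300-gene cell is kept), as are cells whose
mitochondrial-to-endogenous count ratio exceeds 0.1 (strict: exactly 0.1
is kept). Genes with mean normalized expression below 0.01 are then
dropped. The gene filter runs on *normalized* means, after cell
filtering: the same 0.01 bound reappears in variable-gene selection on
normalized data, so a single scale is used for both. Mitochondrial genes
are recognized by a configurable symbol prefix (default `mt-`, the mouse
convention). QC is idempotent.

**Normalization.** $N_{ij} = \ln(1 + 10^4 \, c_{ij} / \sum_i c_{ij})$,
preserving sparse zeros; the identity
$\sum_i (e^{N_{ij}} - 1) = 10^4$ holds per cell.

**Cell-cycle scores.** Score of a phase gene set = mean $N$ over the set
minus the mean over an expression-matched control set: genes are ranked
by mean expression into 25 bins and 100 controls per signature gene are
sampled from the gene's bin (deterministic given a seed). This captures
the essence of the standard scorer — correcting for the expression level
of the signature — without its exact control-pool bookkeeping, which is
not specified to the level of reproducibility anyway. The score
difference (S minus G2M) is the covariate used downstream, so shared
biases cancel.

**Scaling.** Per gene, ordinary least squares of $N$ on UMI total,
mitochondrial ratio and the cell-cycle difference; residuals are z-scored
per gene and clipped at $\pm 10$ to bound outlier leverage. Genes whose
residual standard deviation is below $10^{-10}$ (constant, or fitted
exactly by the covariates) scale to all zeros rather than amplifying
rounding noise. With constant covariates the operation reduces exactly to
per-gene z-scoring.

**Variable genes.** Per gene, mean and dispersion (variance/mean) of
$e^N - 1$; dispersions are z-scored within 20 equal-frequency bins of
mean expression, and genes with mean in $(0.01, 3]$ and z-score $> 0.5$
are kept. Binning is essential: unbinned z-scoring confounds mean and
dispersion because dispersion trends with expression. A single-gene or
zero-variance bin contributes z = 0. The $(0.01, 3]$ window presumes a
transcriptome-scale gene universe (~15k genes at ~10⁴ counts per cell,
putting typical normalized means well below 1). On the 1000-gene
synthetic matrices used here the average per-gene normalized mean is
$\sim 10^4/10^3 = 10$, so the upper bound would discard every gene,
markers included; the analysis drivers therefore run with
`mean_high = Inf` on synthetic data while the function keeps the
real-data default.

**PCA and clustering.** Cells are embedded on the top 25 principal axes
of the variable-gene-restricted scaled matrix; component signs are fixed
(largest-magnitude loading positive) so the embedding is deterministic.
A shared-nearest-neighbor graph (20 Euclidean neighbors including self,
Jaccard edge weights, pruned below 1/15) is partitioned by modularity
community detection — Louvain by default, Leiden as a config switch — at
resolution 0.23 (0.5 for sub-clustering), labels renumbered by
decreasing size. The exact number of clusters at a given resolution is
algorithm- and implementation-dependent, so no test asserts it;
correctness is judged by recovery (adjusted Rand index against the
generator's planted labels) instead.

**Cluster enrichment.** With $C_{ij} = e^{N_{ij}} - 1$,
$\mathrm{logFC}_i = \log_2(\text{mean}_{j \in K} C_{ij} + \varepsilon) -
\log_2(\text{mean}_{j \notin K} C_{ij} + \varepsilon)$. The pseudocount
$\varepsilon = 10^{-9}$ keeps the expression defined when a gene is
absent from one side, preserves rank order, and keeps the two-cluster
case exactly antisymmetric. "Expressed" means raw count $> 0$; markers
require expression in $\ge 20\,\%$ of the cluster's cells, condition
contrasts in $\ge 5\,\%$ of at least one condition (or of at least one
sample, when sample labels are supplied — both readings of the rule are
available, pooled conditions being the default). Ties in ranking break
by gene identifier.

**Signatures and annotation.** For each reference cell type, each
pairwise comparison contributes the genes significant at FDR $< 10^{-4}$,
up-regulated, top 200 by fold change; the signature is the intersection
of all lists (monotone in the list length by construction), with a top-n
override reproducing short signatures. The DE ranker is pluggable — any
function returning per-gene (logFC, FDR) — because full negative-binomial
GLM machinery is deliberately out of scope; the shipped default is a
two-sample t-test on $\log_2(\mathrm{CPM}+1)$ whose pooled variance is
shrunk (prior df 10) toward a lowess mean–variance trend, the standard
moderation that makes small-replicate reference comparisons stable. A
test cross-checks its ranking against an established moderated fit.
Clusters are annotated by the mean, over signature genes, of the
per-gene z-score (across clusters) of mean expression, argmax over
signatures, with the margin reported — the original study states that
signatures were used for annotation but not how, so this scoring is a
documented reconstruction.

## Trajectories

A focal cluster is re-processed *in its own right*: variable genes
re-selected, covariates re-regressed, PCA re-computed on the subset
(consistent with re-clustering a subset separately, and the default
answer to whether centroids live in subset or global PC space), then
clustered at resolution 0.5. Sub-cluster centroids are joined by an
exact minimum spanning tree on Euclidean distances. Kruskal's algorithm
is implemented directly because determinism under ties is part of the
contract: equal-weight edges are taken in lexicographic node-id order.
Tests verify optimality against exhaustive Prüfer-sequence enumeration
of all $n^{n-2}$ spanning trees for $n \le 6$ and against an independent
graph library. The **backbone** is the tree's weighted diameter path —
the natural one-dimensional ordering of transcriptional states — with
ties again broken lexicographically. Each node reports its size and
condition composition; a node whose top condition stays below 50 % is
flagged as dispersed (the original study marks such nodes only
graphically; 50 % is the operationalization chosen here). A single
sub-cluster yields a degenerate one-node trajectory with a warning.

## Bulk filters

CPM and RPKM with the usual definitions (columns of CPM sum to $10^6$;
RPKM is depth-invariant). Expressed genes: CPM strictly greater than 1
in at least two samples. Sample concordance: squared Pearson correlation
of $\log_2(\mathrm{RPKM} + 1)$ over expressed genes — the log base
cancels in the correlation, and the pseudocount of 1 is the documented
choice for keeping zeros finite. The DEG filter takes an *external*
differential-expression table (gene, logFC, FDR) and applies
FDR $< 0.01$ and $|\mathrm{logFC}| > 1.5$, both strict; model fitting
itself (TMM normalization, NB GLMs) is intentionally outside this
package, the table being the interchange boundary. Figure-style
summaries sometimes use FDR $< 0.05$; both cutoffs are plain arguments.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic given their seed.

* `simulate_sc` draws UMI counts gene-wise from a negative binomial
  (dispersion 0.1, typical of droplet data) around log-normal baseline
  means, multiplies each type's 25 marker genes by a fold change
  (default 8) and a condition module (an ISG-like block, default 30
  genes, fold change 6 in IFN-treated conditions), and rescales every
  cell's mean vector to a common expected total — cell types shift
  *composition*, not total RNA content. That rescaling matters: in a
  1000-gene matrix, un-rescaled markers make library size a proxy for
  cell type, and the mandatory regression on UMI totals would then
  remove the planted biology — an artifact of the small synthetic gene
  universe, not a property of real data. Mitochondrial genes are scaled
  to an expected 5 % of each cell's counts.
* `simulate_repertoire` gives each mouse power-law clone frequencies
  ($f_i \propto i^{-\alpha}$, $\alpha = 1$), with the top `n_public`
  ranks occupied by templates shared across all mice — so the expansion
  factor, applied to the top ranks at a chosen timepoint and
  renormalized before an exact multinomial draw, acts on *shared*
  clones. This is the mechanism by which both clonality and cross-mouse
  similarity rise after re-challenge, mirroring a common set of
  tumor-reactive clones. Per-sample totals equal the read depth exactly.
* `simulate_reference_profiles` emulates a sorted-population reference
  compendium: 6 replicate profiles per type at ~4 million reads each,
  NB dispersion 0.04 (biological CV 0.2, the upper end of what is
  expected for genetically identical inbred mice), 20 markers per type
  at fold change 16. Depth and replicate number were fixed by a power
  consideration made once: calling fold-16 markers at FDR $< 10^{-4}$
  with a t-test-family ranker requires per-gene p-values around
  $10^{-6}$, which shallow libraries (shot noise on low-baseline
  markers) or very small $n$ cannot deliver. The generator can plant
  caller-supplied marker sets so reference profiles match a simulated
  single-cell experiment, enabling end-to-end annotation tests.

Not emulated: batch effects, doublets, ambient RNA, realistic CDR3
sequence structure, UMI saturation, or mean–variance relationships
beyond the NB. Passing recovery tests on these simulations therefore
demonstrates the pipeline's correctness and internal consistency, not
robustness to every artifact of real droplet or immunosequencing data.

## Problem sizes

The test suite and the reproduction script run end-to-end recoveries at
400 single-cell profiles × 1000 genes, reference compendia of 5 types ×
2000 genes, repertoire cohorts of 8 mice × 3 timepoints × 10⁵ reads, and
exhaustive MST enumeration up to 6 nodes — sizes at which every oracle
(dense recomputation, enumeration, closed forms) is itself exact and
fast, while preserving the statistical regime (sparsity, depth per gene,
clone-frequency skew) of the full-scale analyses.

## Known limitations

* The SNN/modularity resolution scale is implementation-specific;
  resolutions quoted from other toolkits select comparable but not
  identical granularity.
* The default DE ranker is a moderated t-test on log-CPM, not an NB GLM;
  for real reference compendia with strong library-size or batch
  structure, plug in an external ranker.
* Cell-cycle scoring ships without curated phase gene lists; users
  supply their own (synthetic analyses use planted lists).
* The trajectory backbone is a descriptive ordering of centroids, not a
  pseudotime model; per-cell pseudotime is out of scope.
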