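---
title: "Models and methods behind stromadev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stromadev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromadev)
```

# Scope

`stromadev` re-implements, as a tested and reusable pipeline, an integrative
multi-omics analysis of non-endothelial lymph-node stromal cells: single-cell
subset and trajectory analysis, differentially methylated region (DMR)
detection from whole-genome bisulfite data, differential chromatin
accessibility from ATAC-seq counts, a joint expression-accessibility gene
classification, motif-based transcription-factor (TF) nomination at
trajectory branch points, dynamical gene-regulatory-network (GRN) inference,
and cumulative Z-score matching of TF-overexpression signatures to stromal
subsets. Every module is exercised end-to-end on seeded synthetic generators
that plant a known ground truth, so recovery can be quantified.

The pipeline deliberately starts downstream of read processing: alignment,
peak calling and methylation calling are out of scope; inputs are count
matrices, per-CpG methylation tables and called peak intervals.

# The synthetic generators and what they emulate

Each `make_*` generator is a pure function of its arguments including the
seed, and returns the dataset plus a `sim_truth` record of what was planted.

**`make_sc_dataset`** emulates a developmental scRNA-seq experiment: a
proliferating progenitor pool (20% of cells by default, latent time
$t \in [0, 0.25)$) that bifurcates into two branches ($t \in [0.25, 1]$,
40% each). Genes split into housekeeping background, per-subset markers
(3% of the panel each, shifted $2^{\text{branch\_sep}}$-fold), a cell-cycle
program active in the progenitor pool, and trajectory-dynamic genes — 10% of
the panel rising monotonically with $t$ in every cell plus 15% per branch
rising only along that branch (a 0.3 step at commitment followed by a ramp,
mimicking lineage induction). Dynamic amplitudes are gene-specific, 2-8-fold
at the reference effect size `branch_sep = 2`, and dynamic genes are well
expressed at baseline; both choices reflect real developmental programs,
where lineage drivers swing far more than housekeeping noise. Counts are
negative binomial (dispersion 0.5, the usual scRNA over-dispersion regime)
with log-normal library sizes; library depth is the only batch-like effect
modelled. Doublets, ambient RNA and true batch effects are *not* emulated,
so passing recovery tests here says nothing about robustness to those
artifacts.

**`make_methylome`** plants CpG-island-like DMRs (8-15 CpGs spaced
30-80 bp) on a 10 Mb synthetic chromosome with ~200 bp background CpG
spacing. Background methylation is bimodal (beta mixture); inside a planted
region condition B is shifted by `delta`, directed away from the nearer
boundary of $[0, 1]$ (hypermethylated baselines lose methylation), clamped
with a warning if infeasible. Methylated counts are binomial at Poisson
coverage. No replicate-level biological variance component is added beyond
binomial sampling; the pooled-variance floor in the t-statistic (below) is
what keeps that from degenerating.

**`make_atac`** plants fold changes into a master peak set (half up in each
condition so both signs occur), negative-binomial counts at dispersion 0.2
with log-normal sample size factors, and emits per-replicate peak lists with
10% dropout and up to 50 bp boundary jitter for merge testing.

**`make_motif_hits`**, **`make_overexpression_bulk`** and
**`make_grn_timeseries`** plant, respectively, odds-ratio enrichment of
motifs in chosen gene sets, a $2^{\text{strength}}$-fold up-shift of
signature genes in an overexpression arm, and a linear dynamical system
$x(t+1) = x(t) + w\,x_{\mathrm{tf}}(t) - \alpha\,x(t)$ in which each target
is driven by exactly one TF following a smooth random curve.

# Single-cell core

Quality control retains cells with `min_genes <= detected <= max_genes`
(inclusive; "detected" means raw count > 0, the standard convention) and a
mitochondrial-read percentage at or below the threshold. The three published
parameter bundles are exposed as presets: `ontogeny` (1000-4600 genes,
4.5% mito, 12 PCs, resolution 1.1), `gfspf` (750-4000, 7%, 17, 0.4) and
`irf3` (750-4500, 6%, 30, 0.4).

Normalization is library-size scaling to 10,000 counts followed by
`log1p`; the scale factor is an assumption (the conventional default), as
the source workflow does not state it. Variable genes are ranked by the
residual of a loess fit of variance on mean with a deterministic name
tie-break. Cell-cycle scores subtract the mean of expression-bin-matched
control genes from the phase-set mean, so the null expectation is zero.
Covariate regression is per-gene ordinary least squares (UMIs, percent
mitochondrial/ribosomal reads, S and G2M scores, as configured), dropping
collinear columns with a warning.

Clustering builds a shared-nearest-neighbor graph (k = 20, Jaccard weights,
weak ties below 1/15 pruned) and runs Louvain at the requested resolution.
Per-cluster differential expression is a two-sided Wilcoxon rank-sum of each
gene against all other cells (the source does not name its test; Wilcoxon is
the field default), BH-corrected per cluster — per cluster rather than
globally, another undocumented choice made explicit here. log2 fold changes
compare de-logged means with a pseudocount of 1. Endothelial gating drops
whole clusters whose mean normalized `Pecam1` is at or above 1 (strictly
below survives). Composition heatmaps use a two-step normalization: within
each group the subset fractions correct for unequal group sizes, then each
subset's fractions are renormalized across groups to sum to 100%.

# Trajectory

The principal tree replaces the original latent-graph optimizer (DDRTree)
with a transparent equivalent: PCA, k-means centroids, a Euclidean minimum
spanning tree over the centroids, and projection of every cell onto its
nearest tree edge. The claims exercised here — bifurcation topology, branch
ordering, branch-point differential expression — depend on tree topology and
ordering, not on the specific optimizer. Two numerical details matter:

* **kNN denoising.** Before centroids are fitted, each cell's PC scores are
  averaged over its `n/50` nearest neighbours (capped at 50). This plays the
  latent-space smoothing role of a principal-graph optimizer; without it the
  MST occasionally shortcuts between branch arms on noisy data, inverting
  segment order.
* **Leaf extension.** Terminal nodes are moved outward to the farthest
  projecting cell, so cells beyond the last centroid keep their ordering
  instead of piling up at the node (on a noiseless line the pseudotime order
  is then exact).

Pseudotime is geodesic distance from the root along the tree, normalized to
$[0, 1]$ per tree (units are arbitrary). The root is the node whose
projected cells hold the highest fraction of the earliest timepoint — our
codification of the observation that the proliferating progenitor cluster
forms the starting point — with ties broken by proliferation score, then
smallest node id. Branch labels are the maximal unbranched tree segments;
cells on a branching edge follow their projection offset. `split_by_markers`
assigns each terminal branch to whichever of two markers (Vcam1/Cd34 in the
motivating analysis) has the higher mean normalized expression in it; exact
ties go to an unassigned set. Gene filtering before ordering keeps genes
with mean normalized expression strictly above 0.1.

# DMR detection

CpGs must reach coverage 5 in at least two replicates of one condition.
Smoothing is a coverage-weighted local-linear fit (tricube kernel) over a
window that is the wider of the bandwidth and the span of the
`min_cpg_window` nearest CpGs, clipped to $[0, 1]$; the hot loop is compiled
(C++), and the test suite checks it against a direct weighted-least-squares
fit at random CpGs. Defaults are bandwidth 300 bp and 5 CpGs per window,
chosen to suit the synthetic genome's ~200 bp CpG spacing (the original
toolkit's defaults target sparse mammalian genomes and oversmooth dense
islands — widen both for real data; both are plain arguments).

The per-CpG statistic is a two-group t on smoothed levels with the pooled
standard deviation floored at its genome-wide 75th percentile — a shrinkage
step in the spirit of the original smoothing method, which keeps
near-constant sites from dominating the tails; the exact variance treatment
is not printed in the source and this choice is ours. Regions are built
under four criteria: candidate CpGs beyond the empirical 1%/99% quantiles of
the t distribution, maximal same-sign runs with inter-CpG gaps of at most
300 bp, at least 3 CpGs, and an absolute mean smoothed group difference of
at least 0.25. Quantile cutoffs are computed per contrast over all filtered
CpGs (reference distribution unstated in the source); genomes under 100 CpGs
refuse quantile estimation (pass explicit `cutoffs` instead). Coordinates
are 0-based half-open throughout; a CpG occupies `[pos, pos + 2)` and a
region `[first pos, last pos + 2)`. Pairwise contrasts merge into a
non-overlapping union tagged with contributing contrasts, and promoter
annotation assigns a DMR to a gene when its midpoint lies within 2 kb of the
TSS (nearest TSS wins).

# Differential accessibility

Replicate peak sets merge by 1-bp-overlap union (half-open semantics:
touching intervals stay separate) and any merged interval overlapping the
blacklist by at least one base is dropped — the amount of overlap required
is unstated in the source, so any overlap removes. Normalization is
median-of-ratios size factors against the geometric-mean reference over
regions positive in every sample (library-size fallback with a warning);
the tests verify equality with an independent implementation of the same
estimator.

The differential test is a negative-binomial Wald test: per-region
method-of-moments dispersions pooled within conditions, shrunk halfway
toward a loess mean-dispersion trend, a delta-method standard error for the
log2 ratio of group means (pseudocount 0.5), and BH correction. This is a
deliberately simpler engine than the original tool's Cox-Reid/MAP machinery;
it is validated by simulation calibration (null rejection rate, planted
recovery), not by coefficient-level equality. A region is a DAR when
`padj < 0.05` (strict) and fold change is at least 2 (inclusive, on the
unshrunk estimate — the source does not say whether its threshold applied to
shrunken values). At the planted benchmark (4-fold, dispersion 0.2, three
replicates per condition, mean count 100) the information in the data caps
Wald sensitivity near 0.75 — the standard error of the log2 fold change is
$\sqrt{2\alpha/3}/\ln 2 \approx 0.53$ regardless of depth — and the
reference NB engine run on identical draws performs equivalently; the
package reports its honest sensitivity (~0.78) rather than tuning the
benchmark. Per-gene cumulative fold change is the arithmetic mean of the
signed log2 fold changes of a gene's DARs.

# Integration and TF nomination

Genes are classified by the concordance of the two binary upstream calls
(expression-differential: present in the thresholded DEG table;
accessibility-differential: at least one associated DAR, promoter-annotated
by default): `correlated` (both, same sign), `inducible` (accessibility
only), `active_tf_regulated` (expression only), `unregulated` (neither).
Genes differential in both assays with opposite signs do not fit any of the
three named groups and are labelled `discordant` — an explicit fifth class
rather than a silent coercion. Sign agreement for `correlated` is implied
but not stated by the source's quadrant layout; we require it.

Set enrichment is a one-sided Fisher exact test with BH correction; the
tests pin it to an explicit hypergeometric tail-sum oracle to 1e-12. Motif
enrichment runs over the six class-by-side gene-loci sets (3 classes x
2 "which condition is up" sides) against the accessible-gene universe; a
motif is flagged recurrent when enriched (padj < 0.05) in at least five of
the six sets. TF nomination maps enriched motifs to TFs through a
user-supplied many-to-many table (motif scanning and family collapse are not
re-implemented; how the source collapsed TF families is not defined, so a
family map must be supplied explicitly), intersects with branch-point DEG
tables to compute per-trajectory detected fractions and the
unique/unique/shared Venn decomposition, and optionally unions DMR-proximal
TFs.

# Dynamical GRN

Branch expression is ordered by pseudotime and averaged into 20
equal-occupancy bins; per-bin means form the pseudo-timeseries. For each
target gene $g$ the response $y_t = (x_g(t{+}1) - x_g(t))/\Delta t +
\alpha\,x_g(t)$ is regressed on candidate TF levels at $t$ with a random
forest (100 trees, mtry $=\sqrt{|\mathrm{TF}|}$, seeded); link weights are
total impurity-reduction importances and the global Top 500 links by weight
form the network. A single global decay $\alpha$ (default 0.02 per bin)
replaces per-gene decay estimation — the source states no $\alpha$. Degree
and betweenness come from the directed unweighted link graph. Candidate TFs
are user-supplied; the union of accessibility-derived and DMR-proximal TFs
mirrors the source's construction, whose precise filtering is unstated.

# Signatures and cumulative Z-scores

Bulk differential expression filters to genes with at least 5 reads in at
least two replicates, computes TPM from exon lengths, reuses the NB Wald
engine, and flags DE at |FC| > 2 (strict) and padj < 0.05. Subset signatures
are the Top 100 upregulated DEGs per subset ranked by padj then |log2FC|
with a name tie-break.

The cumulative Z-score is defined in the source without its reference
distribution; this package makes two explicit choices, both configurable in
the sense that the functions are separate and composable: for bulk profiles,
$z$ per signature gene is the change in mean $\log(\mathrm{TPM}+1)$
standardized by the control-arm standard deviation, summed over signature
genes that are DE (non-DE signature genes contribute zero, matching the
"cZscore of DEGs" reading); for single cells, each gene is z-scored across
cells and summed over the set. Genes with zero control variance are skipped
and counted. The interferon-stimulated-gene overlap filters an ISG table to
entries at most 6 h post stimulation with fold change > 2 and p < 0.05
before scoring. Whether the original per-cell score standardized within or
across clusters is unstated; across-cell standardization is used.

# Problem sizes and determinism

The bundled benchmarks run at the scale the recovery claims are stated for:
50,000 CpGs with 50 planted DMRs (plus 100 null methylomes), 5,000 ATAC
peaks with 250 planted DARs (plus 50 null runs), 2,000 cells x 1,000 genes
for trajectory recovery, ten seeded dynamical systems for GRN inference, and
100 arm-label permutations for the cZscore null. All randomness flows from
explicit integer seeds; every generator is reproducible bit-for-bit, and
seeded analysis steps (k-means initialization, Louvain tie-breaks, control
gene sampling, random forests) are pinned the same way.

# Known limitations

* The trajectory model assumes a tree; cyclic or disconnected topologies are
  rejected or mis-fit by construction.
* The NB Wald test is anti-conservative for very low counts with few
  replicates relative to likelihood-based engines; its calibration is
  demonstrated on the synthetic regime (mean counts ~100, 3+3), not for
  single-digit counts.
* The methylome generator omits replicate-level biological variance, so the
  t-statistic floor carries more of the stabilization burden than on real
  WGBS data.
* Cross-dataset integration (anchoring), de novo motif discovery, footprint
  bias correction and GO-graph propagation are intentionally out of scope.
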