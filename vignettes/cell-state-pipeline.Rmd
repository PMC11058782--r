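---
title: "Scoring glioblastoma cell states, therapy-induced signatures, and vascular niche assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring glioblastoma cell states, therapy-induced signatures, and vascular niche assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomastate)
library(dplyr)
```

## The problem this package addresses

Glioblastoma (GBM) tumours are mixtures of transcriptional cell states —
neural-progenitor-like (NPC), oligodendrocyte-progenitor-like (OPC),
astrocyte-like (AC) and mesenchymal-like (MES) — and cells move between
these states under DNA-damaging therapy and under signals from the
vascular niche. Studying that plasticity requires a chain of small,
well-defined computations: score a gene module in every cell against
expression-matched controls, call each cell's state, project cells on a
two-dimensional state map, derive and intersect therapy-induced
signatures, test their enrichment in bulk profiles, correlate signature
surfaces in spatial transcriptomics, estimate kinase activity from
phosphoproteomes, and quantify functional assays (dye dilution,
vascular association, reporter reprogramming) with closed-form rules.
`gliomastate` implements this chain as composable, seeded, tested
functions, together with a synthetic-data generator that emulates the
statistical structure of every input and records its ground truth, so
each step can be validated by recovery rather than by eye.

## Meta-module scoring and the state map

For a gene set $G_j$ and cell $i$, the score is a difference of average
*relative* expressions,

$$\mathrm{SC}_j(i) = \mathrm{av}\,Er(G_j, i) - \mathrm{av}\,Er(G_j^{\mathrm{control}}, i),$$

where $Er$ is log-normalized expression centred per gene across cells.
The control set is built by binning all analysed genes into 30 bins of
aggregate (mean) expression and drawing, for every gene of $G_j$, 100
genes from the same bin. This cancels both cell-level depth effects and
the expression level of the module itself; on the centred layer, the
score of any bin-matched random set has *exactly* zero grand mean over
all cells, so the null calibration checked by the test suite is
structural rather than approximate, and per-cell scores measure genuine
relative activation.

Cells are assigned the state with the highest of the four meta-module
scores. Exact ties are broken by a fixed priority (NPC > OPC > AC > MES)
and flagged; the priority is arbitrary but documented, chosen so that
repeated runs are bit-identical. The two-dimensional "butterfly" map
uses

$$y = \max(\mathrm{SC_{OPC}}, \mathrm{SC_{NPC}}) - \max(\mathrm{SC_{AC}}, \mathrm{SC_{MES}}),$$

with $y > 0$ defining the OPC/NPC half and
$x = \log_2(|\mathrm{SC_{OPC}} - \mathrm{SC_{NPC}}| + 1)$ within it (the
AC/MES difference otherwise). Because $x$ is defined through an absolute
difference, it is reported unsigned and the `family` column indexes the
half-plane; cells with $y = 0$ fall to the AC/MES family and carry a
flag rather than a silent assignment.

```{r score-demo}
sim <- simulate_state_counts(sim_config(n_cells = 600, n_genes = 500,
                                        markers_per_state = 20, seed = 1))
ln <- lognormalize(qc_filter(sim$expr, umi_min = 0, umi_max = Inf))
bins <- bin_by_aggregate_expression(ln)
scores <- score_states(relative_expression(ln), sim$catalog, bins, seed = 1)
coords <- butterfly_coordinates(scores)
table(coords$assigned_state)
```

## Preprocessing choices

Quality control keeps cells with 4000–11000 total UMIs and at most 20%
mitochondrial counts (identified by a configurable `"MT-"` id prefix);
these gates are inclusive on both ends and survivors keep their order
and raw values. Normalization is deliberately the simplest monotone
choice: counts per 10,000, $\log_2(1+x)$. A regression-based
variance-stabilizer with cell-cycle removal would be the richer option
on real data, but the scoring mathematics above only requires a
monotone normalized layer, and the simple transform keeps every
downstream number exactly reproducible from the formulas in this
vignette. Log base 2 is used everywhere (coordinates, fold changes,
ratios) for consistency.

Bulk samples are scaled by unnormalized median-of-ratios size factors:
the factor of sample $j$ is the median over all-nonzero genes of
$k_{gj} / (\prod_j k_{gj})^{1/n}$. Because the geometric means shift
when a sample is rescaled, the factors are meaningful up to a common
constant, and the scale-equivariance property is asserted on factor
ratios.

## Therapy-induced signatures and pre-ranked enrichment

Cluster markers are found per cluster against all other cells with a
two-sided rank-sum test (tie-corrected normal approximation with
continuity correction, verified against `wilcox.test` in the test
suite), keeping genes with log2 fold-change at least 0.5 and expressed
in at least 75% of in-cluster cells. Benjamini–Hochberg adjustment is
applied within each cluster over the retained genes, and the list is
sorted by adjusted p, then |lfc|, then gene id. The top 150 genes form
a therapy signature; signatures from several lines are intersected by
membership counting (`common_upregulated`, genes in at least 3 sets).

Enrichment of a signature in a signed gene ranking uses the weighted
Kolmogorov–Smirnov running sum: with genes sorted by decreasing
statistic, hits advance the sum by $|s|^{w}$ (normalized over hits,
default $w = 1$) and misses retreat by $1/(N - N_h)$; the enrichment
score ES is the extreme deviation, with sign ties within $10^{-9}$
resolved positive so that independent recomputations of the same path
cannot disagree through floating-point noise. Significance comes from
gene-set permutations — `n_perm` random same-size position sets —
because the package has no phenotype replicates to permute at desk
scale; NES divides ES by the mean |null ES| of matching sign, p is the
empirical same-sign tail with an add-one correction, and q is a BH
adjustment over the sets scored in one call. Null distributions are
shared between sets of equal size within a call, which changes nothing
in distribution and makes scoring 500 same-size sets cheap. Paired
longitudinal comparisons are reduced to calls with the q-gate: results
with $q \ge 0.25$ are `no_change` (the boundary belongs to
`no_change`), otherwise the NES sign decides `enriched_up` /
`enriched_down`.

Temporal proteomic trajectories use the same marker sets: the score of
a state at a timepoint is the mean of the finite log2 ratios of its
detected markers — ratios against an empty denominator are infinite and
are excluded, with the number of markers actually used reported.

## Spatially weighted correlation

Each spatial sample is a spot table with grid coordinates, a region
label (`infiltrative_cortex` or `cellular_tumor`) and signature scores
(computed per spot with the same bin-matched scoring). "Spatially
weighted" correlation is realized as Gaussian-kernel smoothing of each
surface within the region (bandwidth 1.5 spot units by default, the
nearest-neighbour scale of a Visium-like grid) followed by Pearson
correlation over the region's spots; at bandwidth 0 it reduces exactly
to plain Pearson, which pins the estimator's meaning. Per-sample
$c \times c$ matrices are stacked into a $(c, c, n)$ array and reduced
by element-wise mean. Constant surfaces have no defined correlation and
are reported as missing with a flag, never as 0.

## Kinase activity from phosphosite fold changes

For kinase $k$ with $m$ detected substrate sites, the activity score is

$$z_k = \frac{(\bar{s}_k - \bar{p})\sqrt{m}}{\delta},$$

with $\bar{s}_k$ the mean substrate log2FC and $\bar{p}, \delta$ the
mean and SD of *all* finite site log2FCs (the background; using all
sites rather than non-substrate sites is the conventional choice and
the difference is negligible when substrates are a small minority).
Kinases with fewer than 5 detected substrates are excluded with a
recorded reason; significance is a two-sided normal p at 0.01. The
statistic is invariant to shifting or positively scaling all fold
changes, which the tests assert directly. Sites with non-finite fold
changes are dropped before any statistic, mirroring the proteomic
score's exclusion rule; sites annotated to several kinases count for
each.

## Functional assay quantifications

* **Dye dilution**: a proliferation dye halves at each division, so
  $2^X = B$ with $B = \mathrm{MFI}_0 / \mathrm{MFI}_t$ and
  $X = \log_2 B$; time per division is elapsed time over $X$. Records
  whose final MFI exceeds the initial beyond a 5% tolerance are labeled
  artifacts and clipped at 0 divisions with a warning.
* **Vascular association**: a cell is attached when its Euclidean
  distance to the nearest vessel polyline is at most a declared contact
  radius (default 5 distance units; the pixel-level contact criterion
  of image-analysis software is not a transferable number, so the
  radius is an explicit parameter). The association of a class is
  attached/total.
* **Vessel co-option**: the same contact rule restricted to
  invasive-front cells, as a percentage.
* **Nuclei and reporter quantities** are plain ratios: % positive
  nuclei in a region, % GFP+dTomato+ among GFP+ cells per timepoint,
  and tdTomato area over total cell area.

## What the synthetic generator emulates — and what it does not

The generator produces every input with known truth, under defaults
that are the package's reference study conditions:

* **Counts** (`simulate_state_counts`): 3000 cells × 2000 genes;
  negative-binomial counts with dispersion $\alpha = 0.5$
  (variance $\mu + \alpha\mu^2$); baseline gene means lognormal
  (meanlog $\log 2$, sdlog 1), which puts library sizes naturally in
  the mid-thousands so the UMI gates act as on real data; four states
  at equal basal proportion 0.225 plus a hybrid intermediate at 0.10
  (the basal hybrid fraction is a free parameter — the biology gives no
  canonical value — and 10% keeps it a clear minority population);
  30 markers per state shifted one log2 unit in their state's cells.
  The hybrid state carries half the effect on both the AC and MES
  marker sets simultaneously, encoding an intermediate position between
  those families. Gene-level parameters always derive from the config
  seed, so samples generated under one config share a gene universe
  whatever their run seed.
* **Treatment** (`simulate_treated_counts`): each non-hybrid cell
  reprograms to hybrid independently with probability
  `reprogram_fraction` (default 0.25); with fraction 0 the output is
  bit-identical to the naive draw under the same seed.
* **Spatial surfaces** (`simulate_spatial_sample`): Gaussian random
  fields (kernel-smoothed white noise, scale 3 spots), standardized and
  empirically orthogonalized *within each region* before mixing to the
  target cross-correlation. Smoothed fields on a 50×50 grid have only a
  few dozen effective degrees of freedom per region, so without this
  calibration the realized correlation of a single sample would scatter
  far around the target; with it, the planted colocalization is an
  exact in-sample property (up to the small observation noise,
  sd 0.1) and recovery tests measure the estimator, not the draw.
* **Phosphoproteome** (`simulate_phospho_table`): background site
  log2FCs $N(0, 0.5^2)$, substrate sites of active kinases shifted by
  the planted effect (effects accumulate when a site has several active
  kinases).
* **Dye dilution** (`simulate_dye_dilution`): exponential halving with
  lognormal multiplicative noise of log-sd `cv`.
* **Vessel scenes** (`simulate_vessel_scene`): straight vessel segments
  in a 2-D field; attached cells are placed within the contact radius
  and unattached cells are rejection-sampled strictly beyond it, so the
  planted class bias is the exact attachment probability rather than a
  lower bound contaminated by chance proximity.

Deliberately not emulated: doublets, ambient RNA, batch effects,
UMI-level read structure, 3-D vessel geometry, segmentation errors and
spatial deformation of tissue. Passing recovery tests on this generator
demonstrates that the estimators invert the stated generative model at
realistic noise; it does not certify performance under artefacts the
model omits.

## Numerical and design choices worth knowing

* Binning for control genes uses mean (not summed) expression on the
  log-normalized layer, quantile-partitioned so bin sizes differ by at
  most one; ties in mean expression break by gene id.
* Control draws are without replacement when the bin holds at least
  `k` genes and with replacement otherwise, preserving the `k × |set|`
  multiset size.
* Signature genes missing from a matrix are dropped with a warning down
  to a hard floor of 50% presence (below it, an error), allowing reuse
  of human sets on other id universes without silently scoring noise.
* `score_states` gives set $i$ the seed `seed + i − 1`, so one seed
  reproduces the whole table and each set still has an independent
  control draw.
* The end-to-end workflow (`run_pipeline`) simulates a naive and a
  treated sample, classifies both, takes the state with the largest
  classified-proportion increase as the therapy-enriched state, builds
  its signature from the naive sample's markers, and tests it on a
  pseudo-bulk treated-vs-naive ranking (three balanced pseudo-replicates
  per condition, median-of-ratios scaling). Every stage writes a JSON
  manifest (parameters, seed, package and R versions, file checksums);
  deterministic stages re-run bit-identically.
* Reference problem sizes used throughout the tests: 3000×2000 for
  state recovery, 500 cells × 100 random sets for null calibration,
  1000-gene rankings with 50-gene sets (500 permutations for power, 50
  simulations; 500 sets at 2000 permutations for calibration), 50×50
  spatial grids, 100 phospho simulations, 200 dye records. These sizes
  make every property measurable with tight Monte-Carlo error while the
  whole suite stays comfortably interactive.

## Known limitations

The marker test is a normal-approximation rank-sum, adequate from a few
dozen cells per group but not for very small clusters; enrichment
permutes gene sets, not phenotypes, so its null ignores inter-gene
correlation within real samples; the spatial weighting is a declared
kernel choice, not a reconstruction of any particular neighbour-
dependency correction; and the contact radius in vessel quantifications
is a parameter the user must set to match their imaging scale.
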