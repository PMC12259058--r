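---
title: "Methods: single-cell spatial neighborhood quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell spatial neighborhood quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbhood)
```

## The model

A multiplexed immunofluorescence experiment is reduced to a *marked point
pattern*: each segmented cell *i* has a position $(x_i, y_i)$ in micrometers
(image convention, origin top-left) and marks — per-marker mean intensities,
a phenotype label, and a lipid-stain flag. All of the package's spatial
statistics are functions of Euclidean center-to-center distances
$d_{ij} = \lVert (x_i,y_i) - (x_j,y_j) \rVert$, so the analysis is invariant
under rigid motion of the frame and covariant under rescaling.

**Phenotyping.** Labels come from an ordered list of marker-predicate rules.
A predicate is `marker > t` (positive) or `marker ≤ t` (negative) against a
user-supplied threshold *t*; a cell receives the first rule whose predicates
all hold, or the fallback label ("double negative") if none do. The order
matters and is part of the panel definition: in the shipped immune panel the
MDSC rule (CD68+/CD11b+/HLA-DR−) precedes the generic TAM rule (CD68+), so
first-match-wins reproduces the intended hierarchy. Positivity is strict
(`>`): intensity 0 against threshold 0 is negative, which keeps the boundary
case well defined. Thresholds are deliberately *inputs*: they depend on
staining chemistry and acquisition settings, and the package makes no
attempt to learn them.

**Neighborhoods.** Two cells are neighbors when $d_{ij} \le r$ with
$r = 55\,\mu m$ by default — roughly two to three cell diameters, the scale
at which juxtacrine and short-range paracrine interaction is plausible. The
boundary is inclusive: "maximum distance $r$" is read as attained. For each
focal cell the package computes neighbor counts and fractions by phenotype,
the distance to the nearest cell of a target type (self excluded), the mean
distance to the $k$ nearest targets ($k = 10$ default), and the
lipid-loaded-macrophage metrics. Nearest-of-type searches are unbounded by
default — nothing in the definition caps a nearest-neighbor distance at the
neighborhood radius, and observed group means can exceed it — with an
optional within-radius policy that censors beyond $r$.

**Border exclusion.** A focal cell closer than $r$ to the ROI boundary has a
truncated neighborhood, which would bias composition fractions and distances
downward near the edge. Such cells are therefore removed *as focal cells*
but remain eligible as neighbors and targets of retained cells: the
truncation argument concerns the focal neighborhood only, and discarding
edge cells as neighbors would bias retained neighborhoods instead. On a
$W \times H$ rectangle the retained set is exactly the inset rectangle
$[r, W-r] \times [r, H-r]$; polygonal ROIs use exact point-to-edge distances
with an even-odd inside test, with the rectangle as a fast path.

**Aggregation.** Metrics are computed per focal cell. Group summaries are
reported at two levels, because they genuinely differ on unbalanced data:
`per_roi_then_pool` averages cells within each ROI and then averages ROI
means (each tissue region weighs equally — robust when ROIs differ greatly
in cell count), while `pooled_cells` weighs every cell equally. Neither is
canonically right; both are exposed and labeled, with `per_roi_then_pool`
the default. Fold changes are ratios of group means, reported in both
orientations. Group comparisons use the unpaired t test, Welch variant by
default (the equal-variance assumption is rarely defensible across tissue
regions); p-values are nominal, with no multiplicity correction.

## Algorithms and numerical choices

The fixed-radius neighbor relation is computed with a grid-bucket search:
cells are binned into an $r$-sized grid so candidates are confined to the
3×3 block of bins around each cell, giving near-linear work at tissue-scale
densities. Nearest and $k$-nearest queries use chunked vectorized distance
blocks (bounded memory). The test suite verifies both against exhaustive
$O(n^2)$ distance-matrix recomputation — exactly, not to a tolerance: the
same IEEE operations are performed, and $k$-nearest means are accumulated in
ascending order so summation order is reproducible.

Other conventions: missing values propagate as `NA` with counts reported —
a focal cell with fewer than $k$ targets yields a missing $k$-nearest mean
rather than a partial mean, which would bias low; a focal cell with zero
neighbors has an empty composition flagged as such; a region class with no
target cells reports missing distances and a missing mean. In quantile
gating, cells tied exactly at a gate boundary are all included (with a
warning) — deterministic, at the cost of occasionally exceeding
$\lceil f\,n \rceil$ members; constant intensities are an error. When the
top and bottom ceilings jointly exceed $n$ (0.5/0.5 on odd $n$), the low
gate yields one cell so the partition stays disjoint.

## The synthetic tissue generator

`tissue_config()` + `generate_tissue()` emulate the spatial structure the
analysis is designed to detect: tumor niches enriched in macrophages over a
background. The field is a $W \times H$ rectangle with non-overlapping disk
niches. Tumor cells follow a homogeneous Poisson process of density
$\lambda_{tumor}$ over the whole field; inside a niche a tumor cell is a
resistant persister (TRPC) with probability `trpc_in_niche_fraction`,
otherwise a sensitive cell (TSC). Macrophages have density $\lambda_{TAM}$
in the background and $\rho\,\lambda_{TAM}$ inside niches. Counts are
Poisson draws from area × density — so density expectations are exact and
closed forms exist — with a fixed-count mode for deterministic tests.
Positions are uniform within their region (rejection sampling for the
background, polar sampling within disks). Lipid flags are Bernoulli with
per-(type, region) probabilities; marker intensities are truncated Gaussians
with well-separated positive/negative components per type, so threshold
classification recovers the generating type essentially perfectly. Draws
happen in a fixed block order (background tumor, niche tumor, background
TAM, niche TAM) from a single seeded stream, so outputs are reproducible and
stable under downstream changes.

Defaults were chosen once as a realistic glioblastoma-like regime: a
1000 × 1000 µm field with four 150 µm niches (≈28% of the field) and
densities $\lambda_{tumor} = 0.003$, $\lambda_{TAM} = 0.0012$ cells/µm²
(≈4,700 cells per tissue — the scale of a large imaging ROI, and the size at
which recovery experiments over tens of seeds stay cheap); enrichment
$\rho = 2.5$, matching the magnitude of macrophage-infiltration fold changes
the pipeline is meant to resolve; lipid probabilities 0.746 (TRPC), 0.30
(TSC), and 0.774/0.586 (TAM in niche/background), the regime of reported
lipid-loading contrasts in glioblastoma tissue; and
`trpc_in_niche_fraction = 0.8`, reflecting that resistant-cell regions are
identified by marker enrichment, not purity (no published value exists; the
analysis is insensitive to it because region membership is ground truth).

`expected_metrics()` provides the closed forms used for recovery testing
(available only for non-overlapping niches): lipid fractions equal their
configured probabilities; the niche/background TAM *density* ratio is
$\rho$; and the expected fraction of a neighborhood that is TAM, deep inside
a region, is the density mix $f = \lambda_{TAM}^\*/(\lambda_{TAM}^\* +
\lambda_{tumor})$ with $\lambda_{TAM}^\* = \rho \lambda_{TAM}$ inside
niches. Recovery tests compare the pipeline estimate of
$f_{niche}/f_{background}$ with this closed form, restricting focal cells to
at least one neighbor radius inside (or outside) the niche boundary via
`region_of_cells()`: a focal cell near the boundary has a mixed
neighborhood, and including the boundary ring would bias the ratio toward 1
by construction rather than through any fault of the estimator.

What the generator does *not* emulate — segmentation error, marker
spillover, intensity spatial gradients, cell-shape effects, or clustered
(non-Poisson) positioning within a region. Passing recovery tests therefore
demonstrates correctness of the measurement pipeline on its assumed data
model, not robustness of thresholds or segmentation on real images.

## DSP probe QC

For spatial-profiler count matrices the package implements the probe-level
QC arithmetic: per-segment signal-to-background ratios (count divided by the
geometric mean of the segment's IgG negative-control counts — the IgG
probes' own ratios then have geomean exactly 1), the four per-segment
normalization factors (housekeeping geomean, IgG geomean, area, nuclei), and
factor concordance as the sample SD of per-segment $\log_2(a/b)$ ratios — a
geNorm-style stability measure, invariant to rescaling either factor and
exactly 0 for proportional factors. Normalization divides counts by the
factor and multiplies back by the factor's geomean over segments so the
output stays on the raw-count scale; recomputing the factor on the
normalized table gives a constant — the fixed point the tests check.
Probe filtering excludes targets whose ratio stays at or below a background
band in all but fewer than a minimum number of segments; the band (default
1.5) and the minimum (default 1) are exposed flags, since the underlying
criterion is qualitative. Zero counts are an error by default (geometric
means are log-based); a configurable pseudocount is available. Geomeans are
computed before probe filtering by default.

## Problem sizes and limitations

Validation experiments in the test suite use random instances up to 2,000
cells for oracle equivalence, ~5,000-cell tissues over 20 seeds per
enrichment level for parameter recovery, ~2,000 cells per class for
lipid-fraction recovery, and 200 replicates for t-test calibration — sizes
chosen to estimate each quantity comfortably within its tolerance.

Known limitations: phenotype thresholds are inputs, not learned; the
neighborhood radius is global, not adaptive to local density; no spatial
enrichment testing (permutation nulls, Ripley's K) is provided, since the
quantification itself makes no inferential claim; and polygon ROIs must be
simple. Whether composition percentages should be averaged per focal cell or
pooled over all neighborhoods is unspecified in common practice; both are
computed and labeled, and users should report which they used.
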