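---
title: "heatcompose: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{heatcompose: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcompose)
```

This vignette is the package's own account of the science and engineering
behind it: the models each component implements, the parameters that matter,
what the synthetic data emulates, and the decisions taken where several
defensible designs existed.

## Color mapping

A continuous mapping is the function defined by strictly increasing breaks
$b_1 < \dots < b_k$ and anchor colors $c_1,\dots,c_k$: inside $[b_i,
b_{i+1}]$ each channel is interpolated linearly in a chosen color space, at a
break the anchor is returned *bit-exactly* (values landing exactly on a break
bypass interpolation so 8-bit rounding can never perturb them), and values
outside the break range clamp to the end colors. Clamping makes mappings
idempotent under clamping — `map(x) == map(clamp(x))` — which is what makes
a mapping shared between heatmaps a genuine common scale.

The default interpolation space is CIE Lab, chosen because equal coordinate
steps are approximately equal perceptual steps, so two-anchor ramps do not
develop the mid-ramp brightness bulges that plain sRGB interpolation
produces; sRGB and HSV are available for users who want the classic
behavior. Missing values map to mid grey (`#808080`), visible on both light
and dark ramps. Categorical matrices use an exact level-to-color table; the
default palette is a fixed qualitative cycle keyed to *sorted* level order,
so identical level sets color identically without any seed.

## Ordering

Hierarchical clustering is delegated to `stats::hclust` (the field's
reference implementation); the package contributes the surrounding policy.
Defaults are euclidean distance with complete linkage; "pearson" distance is
$1 - r$ on item vectors with pairwise-complete observations, and users may
supply a pairwise function, a whole-matrix distance function, or an already
built tree (`dendrogram`, `hclust`, or a minimal nested merge list), so trees
edited elsewhere integrate directly.

Dendrogram reordering rotates children so the subtree with the smaller mean
leaf weight is on the left; ties keep the incoming order, and the default
weights are the item means of the matrix. The operation preserves the merge
structure (the multiset of merge heights is untouched), which the tests
assert as an invariant.

## Splitting

Three mechanisms produce an ordered partition of an axis ("slices"):

* **Consensus k-means** (`row_km`/`column_km`). A single k-means run depends
  on its starting centers; consensus damps this. The procedure is: run
  `stats::kmeans` `repeats` times (default 10) with seeds `seed + 0 …
  seed + repeats − 1`; form the co-association matrix $C_{ij}$ (fraction of
  runs assigning $i$ and $j$ together); average-linkage cluster $1 - C$ and
  cut into $k$ groups. This is a standard consensus-clustering construction,
  chosen because it is deterministic given the seed and degrades gracefully:
  with `repeats = 1` it reproduces a single seeded run. Missing values are
  imputed by column means for the clustering only, and a log line says so.
* **Categorical combinations.** One slice per *observed* combination of the
  supplied label vectors, labeled by the levels joined with `","` and
  ordered lexicographically over the level orders.
* **Dendrogram cutting.** The tree is cut at the height yielding exactly
  $k$ groups (the $k-1$ highest merges removed). If tied merge heights
  straddle that boundary, exactly $k$ groups is not achievable by any height
  cut; the package refuses and lists the attainable counts rather than
  silently returning a different $k$. The resulting partition is invariant
  under branch rotation, which the tests assert.

When clustering is on, it runs independently inside each slice and a second
clustering over the slice mean vectors (average linkage, then mean-weight
reordering) fixes the slice display order. Where slice order from a
categorical split interacts with slice-level clustering, the slice-level
clustering wins — the slices exist to be compared, so ordering them by
similarity of their means is the informative choice. K-means slices are
relabeled `"1"…"k"` along the final display order so the labels read
top-to-bottom.

## Annotations

Tracks are pure functions from (payload, display order, slice sizes) to
drawing primitives. This purity is the extensibility contract: because a
renderer sees only the permuted payload and the positional slices, rendering
with an order equals rendering the pre-permuted payload with the identity
order — an equality the test suite checks literally (`identical()` on
primitive lists) for every built-in kind, and which holds for any user
renderer that honors the contract.

Numerical choices per kind: smoothed lines use loess with span 0.75 and
degree 2 (the `stats::loess` defaults); boxplots use `boxplot.stats`
(1.5 IQR whiskers, outliers drawn); violins and joyplots use
`stats::density` defaults, joyplot peaks may overflow into neighboring bands
(scaled to twice the band by default) and are clipped only at the block
boundary; horizon charts cut the area chart at multiples of the band height
`H` (default `max(|x|)/n_bands`) and overlay the bands, negatives mirrored
in a red ramp — `horizon_bands()` exposes the decomposition for testing.
Percent tracks print the rendered fraction to one decimal.

**Mark labels.** The goal is stated simply — shift labels just enough to
remove overlaps — but needs an objective to be well-defined. The package
minimizes the sum of squared displacements from the anchors subject to
order preservation, non-overlap and the track bounds. Substituting
cumulative minimum spacings turns this into isotonic least squares with box
constraints, solved exactly by pool-adjacent-violators plus a clamp.
Least squares was chosen over, e.g., minimax displacement because it keeps
isolated labels pinned at their anchors and spreads cost smoothly through
conflict runs; the tests verify the solution beats 1,000 random feasible
layouts and matches an independently coded run-pooling solver.

**Link panels** allocate extents proportionally to subset size, floored at a
minimum panel size with iterative renormalization, and require subsets to be
contiguous in display order (anything else would need crossing quads).

## Lists and layout

`+` and `%v%` build a list model; the main heatmap — first numeric heatmap
unless overridden — imposes its aligned-axis permutation and slices on every
member. A member's own conflicting request is discarded with a log record:
silent override was judged worse than noisy override, and failing would make
innocent compositions (two independently clustered heatmaps) an error.

Layout gives fixed absolute sizes to dendrograms (0.6 in), name strips,
titles, annotation tracks and legends, and lets the body absorb the rest, so
exported figures have predictable component geometry at any device size;
slice gaps default to 2.5% of the body extent. Component placement follows
the conventional arrangement (column dendrogram top, row dendrogram left,
column names bottom, row names right, legends right). Every component's
region is recorded by name in the scene, and `decorate()` re-enters a named
region to overlay user primitives, preserving prior content.

Rendering: the package serializes SVG itself with fixed number formatting
and no timestamps or generated ids, so equal models give byte-identical
files — determinism of vector output is part of the package's contract and
is tested by hashing. PNG and PDF go through the standard `grid` devices.

## Rasterization

With an `n_r × n_c` matrix in a body of `p_r × p_c` device pixels, per-cell
vector drawing is wasted (and file-bloating) whenever `n_r > p_r` or
`n_c > p_c`. Three reductions are offered: (1) offscreen render at pixel
resolution — each pixel center samples the cell covering it; (2) aggregate
the matrix to `p_r × p_c` by even block partitioning (row `i` to block
`⌊(i−1)·p_r/n_r⌋+1`) with mean/median/max/min/random summaries, colors
mapped after aggregation; (3) render at one pixel per cell and resample with
nearest, bilinear, or 3-lobe Lanczos filters (the kernel widened by the
downscale factor, the standard anti-aliasing choice). The default policy is
`auto`: strategy 1 once the body exceeds 10^6 cells — large enough never to
surprise users with small matrices, small enough that files stay tractable.
The `random` aggregator draws through the seeded RNG for reproducibility.

## High-level plots

**Density heatmap.** Each input distribution becomes one column of Gaussian
kernel density estimates (Silverman's rule bandwidth, 500 grid points — the
`stats::density` conventions) on a grid spanning the pooled range. Columns
may be clustered by the two-sample Kolmogorov–Smirnov statistic, a natural
distribution distance that is symmetric, non-negative and zero iff the
empirical distributions agree.

**3D heatmap.** Cells become bars; height scales with value, face color
comes from the mapping (encoding both is recommended since projection
distorts height comparison). Projection is cavalier oblique at 45° with
depth scale 0.5; bars paint back-to-front (row 1 farthest), right-to-left
within a row so depth overhangs never hide nearer bars.

**oncoPrint.** A sample with several alteration types in one gene counts
once in the ordering statistics (the ordering asks "is this gene altered
here", not "how often"). Genes sort by decreasing altered-sample count;
samples then sort by decreasing lexicographic rank of their binary
alteration vector over the ordered genes (memo sort) — the classic
formulation that produces the mutual-exclusivity staircase. All ties keep
input order, making the ordering stable and idempotent.

**UpSet.** `distinct` (exact membership), `intersect` (superset) and
`union` (any) modes are computed from element bitmasks; elements in no set
are excluded. The genomic mode flattens each list, segments the genome at
the union of all breakpoints, assigns each segment a membership vector and
sums segment lengths — sizes are reported in base pairs, since regions of
very different lengths make region *counts* misleading. All coordinates are
0-based half-open internally; readers convert at the boundary.

**Genome tracks and enrichment.** `bin_genome` tiles chromosomes with
fixed-width windows; `signal_to_bins` supports overlap-weighted means over
the *covered portion only* (an uncovered bin is missing, not zero — zero is
a value, absence of data is not), coverage fractions, and maxima.
`normalize_to_targets` anchors windows at the target start (end for
minus-strand targets, i.e. the TSS of a minus-strand gene) and reverses
minus-strand rows so upstream is always leftmost; categorical signals yield
one coverage-fraction matrix per category. `enriched_profile` is the
column-wise mean per row slice with missing values excluded per column.

## Synthetic data

All demonstrations and tests run on seeded generators because the plots'
correctness properties (partition exactness, order invariants, per-base
agreement) are data-independent; what the generators provide is *known
ground truth*:

* `fixture_grouped_matrix` — unit-variance Gaussian noise around planted
  group-mean offsets (default 5 sd between row groups, n = 60 split into
  equal groups): comfortably separable, so exact recovery is the correct
  expectation and any failure indicates a defect, not noise.
* `fixture_alteration_table` — per-gene Bernoulli alteration rates with an
  optional engineered mutually exclusive block.
* `fixture_interval_lists` — exponential-length intervals at a target
  coverage on toy genomes (≤ 10 kb in tests, so a per-base oracle is
  affordable).
* `fixture_signal_track` — piecewise-constant signal with triangular boosts
  around anchors, emulating TSS-centered enrichment.
* `fixture_distributions` — columns drawn from normal and uniform families.

What they do *not* emulate: heavy-tailed expression distributions,
correlated noise, batch structure, chromosome-scale coverage biases, or
realistic mutation spectra. Passing tests therefore demonstrate algorithmic
correctness and reproducibility, not robustness to every property of real
cohort data; on real data the same code paths run, but clustering quality
and visual legibility depend on the data itself.

## Problem sizes and limitations

The routine test suite works at desk scale — axes of 4–64 items for
oracle-checked properties, a 600×600 matrix for the rasterization
file-size containment check — and the acceptance checks add a 2,000×2,000
matrix for the vector-versus-raster comparison and n = 10,000 samples for
the KDE calibration; these sizes were chosen so each property is exercised
well above its edge cases while the full suite stays fast enough to run on
every change.

Known limitations: text metrics in SVG are approximations (no font shaping),
so long labels can collide visually even though layout boxes do not overlap;
HSV interpolation takes the naive hue path; image annotations read PNG only;
the configuration schema exposes the common options, with the full surface
available through the API; Shiny-style interactivity is out of scope by
design.
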