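# heatcompose

Cluster heatmaps are the workhorse of matrix visualization in genomics:
expression, methylation or signal matrices are reordered by hierarchical
clustering so that rows and columns with similar patterns sit together, and
color carries the values. Real analyses rarely stop at one matrix — clinical
covariates ride along as annotation tracks, several data types must share one
row ordering, gene panels need oncoPrints, region lists need UpSet plots, and
ChIP-seq or methylation signal is summarized around transcription start
sites. `heatcompose` is a composition engine for exactly this kind of figure,
aimed at bioinformaticians who need reproducible, scriptable heatmap layouts
rather than one-off plots.

## What it implements

**Exact color mapping.** A mapping is defined by strictly increasing breaks
`b_1 < … < b_k` and anchor colors `c_1, …, c_k`; for `x` in `[b_i, b_{i+1}]`
the color is the channel-wise linear interpolation of `c_i` and `c_{i+1}` in
a chosen color space (perceptual Lab by default), with `map(b_i) = c_i`
exactly and clamping outside `[b_1, b_k]`. Two heatmaps given the same breaks
and colors are therefore directly comparable.

**Ordering and splitting.** Rows/columns are ordered by agglomerative
clustering (any `stats::hclust` linkage, euclidean or `1 − r` Pearson
distance, or user-supplied distance functions or externally built
dendrograms), then branches are rotated so the subtree with the smaller mean
value sits left/top. Bodies split three ways: consensus k-means (k-means run
`R` times with consecutive seeds; the co-association matrix `C_{ij}` =
fraction of runs co-clustering `i` and `j` is average-linkage clustered on
`1 − C` and cut at `k`), categorical level combinations, or cutting the
dendrogram into `k` subtrees. After splitting, clustering runs inside each
slice and a second clustering over slice means orders the slices.

**Annotations.** Sixteen track kinds (simple heatmap-like tracks, points,
lines, loess-smoothed lines, stacked barplots, percent bars, boxplots, text,
histograms, violins, joyplots, horizon charts, images, mark labels, linked
panels, textboxes) attach to any side and are automatically permuted and
sliced with the heatmap. Mark labels solve an order-preserving least-squares
displacement problem (pool-adjacent-violators) so labels never overlap.

**Lists.** `a + b` concatenates horizontally, `a %v% b` vertically; the main
heatmap (first numeric one by default) imposes its ordering and splitting on
every member.

**Rasterization.** Very large bodies are reduced to device pixels by one of
three strategies: offscreen rendering at pixel resolution, block-aggregating
the matrix before color mapping (mean/median/max/min/random), or rendering at
one pixel per cell and resampling (nearest/bilinear/Lanczos).

**High-level plots.** Density heatmaps (Gaussian KDE columns on a shared
grid, optional column clustering by Kolmogorov–Smirnov distance), 3D bar
heatmaps with painter's-algorithm occlusion, oncoPrints (genes sorted by
altered-sample counts, samples memo-sorted by lexicographic rank of their
alteration vectors to expose mutual exclusivity), UpSet plots in
distinct/intersect/union modes over element sets or base-pair-resolved
genomic region lists, genome binning with signal normalization, and
TSS-anchored enrichment matrices with per-slice average profiles.

Output is SVG (serialized by the package, byte-deterministic), PNG or PDF. A
YAML plot configuration plus a CLI (`inst/cli/heatcompose`) cover scripted
use; seeded fixture generators reproduce every demonstration dataset class.

## Worked example

```r
library(heatcompose)

fx <- fixture_grouped_matrix(n_rows = 60, n_cols = 12, k = 3, delta = 5, seed = 1)
hm <- heat_map(fx$matrix, name = "expr", row_km = 3, seed = 1,
               top_annotation = annotation_block(
                 group = rep(c("a", "b"), each = 6), axis = "column"))
hm
#> <heat_map> 'expr': 60 x 12 (numeric)
heatmap_slices(hm, "row")
#> <slice_spec> row axis, 3 slice(s): 1[20] 2[20] 3[20]
draw(hm, "demo.svg", width = 6, height = 6)
#> <hm_scene> 6 x 6 in, 11 region(s)
```

The fixture plants three row groups separated by 5 noise standard
deviations; consensus k-means recovers them exactly, so the three slices
hold 20 rows each. The scene records 11 named component regions (body
slices, dendrograms, annotation, names, legend) that `decorate()` can
revisit after drawing.

```r
region_upset(list(A = genomic_intervals("chr1", 0, 100),
                  B = genomic_intervals("chr1", 50, 150)))$combinations[, 1:3]
#>   combination degree size
#> 1           A      1   50
#> 2           B      1   50
#> 3         A&B      2   50
```

Two 100-bp interval lists overlapping by 50 bp decompose into 50 bp unique
to each list and 50 bp shared — sizes are summed segment lengths in base
pairs (0-based half-open coordinates throughout).

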