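---
title: "Methods: spatial analysis of multiplexed tissue protein images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial analysis of multiplexed tissue protein images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmux)
```

# The problem

Imaging mass cytometry (IMC) and related multiplexed tissue imaging
modalities produce one intensity image per protein marker — typically 20–40
channels at ~1 µm/pixel over a 2500 × 2500 µm region of interest — plus a
cell segmentation mask. Two complementary questions arise at different
scales. Bottom-up: what does each segmented cell express, how do marker
pairs correlate across cells, and how do those statistics differ between
conditions (e.g. healthy vs chronically inflamed tonsil)? Top-down: which
markers co-localize into anatomical compartments (germinal centers, crypts,
surface epithelium), and how far apart do the cell populations of different
markers sit in physical space?

`spatialmux` implements both pipelines on shared conventions, and ships a
synthetic tissue-phantom generator so every stage can be validated against
planted ground truth without any real acquisition.

# Conventions and units

All coordinates are 0-based `(row, col)` pixel positions, matching the
image-array convention. Every physical distance is `pixels × pixel_size_um`
(default 1 µm/pixel); a 5-pixel distance at 1 µm/px is 5 µm, by definition
and by unit test. Intensities are raw counts and are never rescaled on
read, because the binarization threshold below is defined on raw counts.
Segmentation labels are arbitrary positive integers: they need not be
consecutive and are never renumbered, since real segmentation exports skip
labels.

# Bottom-up: single-cell quantification and statistics

`quantify_cells()` reduces each labeled cell to the unweighted mean of its
member pixel coordinates (centroid) and the mean intensity of its member
pixels per marker — the MeasureObjectIntensity convention, so tables from
external segmentation pipelines drop in directly.

**Positivity.** The field's exports do not define when a cell "expresses" a
marker, but the percentage-count statistic requires one. We call a cell
positive when its mean intensity is *strictly greater* than the marker's
threshold, and default every marker's threshold to the same 60-count value
used for mask binarization. This is the least-invention choice: one
threshold, one comparison convention, shared by the pixel-level and
cell-level analyses, overridable per marker via
`analysis_config(positivity_threshold = )`.

**Percentage count** is cells positive for a marker divided by cells
positive for *at least one* marker. No cross-marker normalization is
implied; the fractions of different markers can sum above 1.

**Correlation.** `marker_correlation()` computes Pearson r over all cells'
mean intensities (no positivity gating, matching the whole-ROI cell counts
such statistics are usually quoted with; a `positive_only` flag gates to
cells positive for either marker). Two correlations from independent
samples are compared by the Fisher Z-transformation,

$$ z = \frac{\operatorname{atanh}(r_1) - \operatorname{atanh}(r_2)}
           {\sqrt{1/(n_1-3) + 1/(n_2-3)}}, $$

with a two-sided normal p-value. Distribution shifts are tested with the
asymptotic two-sample Kolmogorov–Smirnov statistic (sample sizes in the
intended uses are in the tens of thousands, so the asymptotic p-value is
appropriate and no permutation scheme is offered).

# Top-down: anatomy by k-means on binarized masks

Each marker image is binarized at the shared threshold (strict `>`), and
the *markers* are clustered: the data matrix is `n_markers × n_pixels`,
each row a flattened 0/1 mask. k-means over this matrix groups markers by
where — and how much — they are expressed, so each cluster is a proxy for
an anatomical compartment. The module clusters markers, never pixels.

Numerical choices, made once:

* Engine: Lloyd's algorithm (`stats::kmeans`) with `n_init = 10` restarts,
  keeping the lowest-inertia solution, `max_iter = 300`. A tolerance value
  is carried in the configuration for completeness, but Lloyd's stopping
  rule here is assignment stability.
* Rows are canonicalized by sorted marker name before clustering, and the
  restart centers are sampled from the *distinct* mask patterns. Binary
  masks are frequently duplicated (markers sharing a compartment), and
  sampling raw rows both risks empty clusters and makes the result depend
  on input order; sampling distinct patterns removes both problems, so the
  assignment is invariant to marker reordering at a fixed seed. Restarts
  that still empty a cluster are discarded.
* `K` defaults to 6 (the typical number of visually distinct compartments
  in tonsil-scale data) and is always user-set; there is no automatic K
  selection.
* An optional stride subsamples pixels for very large ROIs; the default is
  the exact full-resolution path.

The **area ratio** of a marker is its positive-pixel count over the total
pixel count. Display composites take each cluster's pixel-wise mean image,
rescale the 2nd–98th percentile band to [0, 1] (a degenerate band maps to
zero — a constant image carries no contrast), tint each cluster with an
evenly spaced rainbow hue, and combine layers by per-pixel channel maximum
so each region keeps its own hue.

# Spatial distances and proximity

Cells enter a marker's point set through the positivity call. All
distances are Euclidean on centroids, reported in µm.

`knn_mean_distance()` averages, over every query cell, the distances to its
`k` nearest reference cells (default `k = 10`). `k` clamps to the reference
set size rather than erroring, because sparse markers are routine. When
query and reference are the same set, exact self-pairs are excluded. The
pairwise marker matrix stores both directed entries — nearest-neighbor
means are direction-dependent — and undirected summaries (intra-cluster
edges) average the two directions. Inter-cluster distance averages all
directed entries between the two clusters' marker pairs.

Proximity maps connect each origin cell to its single nearest destination
cell (ties broken by lowest index, for determinism); using nearest rather
than all-pairs distances keeps the statistic unbiased by marker area and
density, and the test suite asserts the nearest-link mean never exceeds
the all-pairs mean. The link histogram uses 20 equal-width bins spanning
`[0, max]`, right-closed with the lowest edge included; all-zero distances
degenerate to a single bin at 0. The companion summary statistic is the
fraction of nearest distances strictly below a 30 µm cutoff — roughly
cell-contact range at 1 µm/pixel.

# Topographic maps

`make_topography()` smooths an intensity image with a separable Gaussian
(default σ = 5 px) and downsamples by a stride (default 4), sized so
full-scale ROIs reduce to desk-scale grids; contour levels are evenly
spaced between the height extremes. The convolution pads by symmetric
reflection: replicate or circular boundaries would dim or wrap border
structure and shift peaks near edges, and reflection preserves total mass
to well under 0.1 % for interior structure.

Peaks are strict 8-neighbor local maxima above a height floor, kept
greedily in descending height under a minimum-separation constraint, and
reported in original pixel coordinates. "Distance between the peaks of two
markers" is operationalized as nearest-neighbor matching from the first
peak set to the second, averaged — the simplest defensible reading; an
optimal-assignment matching would be an alternative and is deliberately
not offered, to keep the statistic interpretable. For singleton peak sets
the measure is symmetric.

# Network maps and the fixed-landmark reference

Cluster graphs carry node size = area ratio (markers) or mean member area
ratio (cluster nodes), and edge weight = mean k-NN distance. Normalized
weights are min–max scaled over the weighted edge set so a red-to-blue
colormap reads relative closeness; a single-edge graph normalizes to 0 to
avoid 0/0. Inter-mode graphs use cluster-level nodes for the weighted
cluster-pair edges and attach marker nodes by unweighted membership edges
(excluded from normalization).

The layout is a hand-implemented Fruchterman–Reingold spring model in the
conventional parameterization: optimal distance `k`, per-pair repulsion
`k²/d`, per-edge attraction `w·d²/k`, displacement capped by a temperature
that cools linearly from one tenth of the initial frame over the iteration
budget. Cluster maps use `k = 0.3`, 30 iterations; the reference framework
uses `k = 3.0`, 5 iterations. No installed graph library exposes this
parameterization with hard-fixed nodes, which is why it is implemented
here; a small-step force-balance simulation serves as its oracle in the
tests. Positions are returned in force-model units with no cosmetic
rescaling — rescaling would break comparability of fixed-landmark frames
across datasets. Edge weights default to 1 in the layout; distances
influence the drawn edge colors, not the attraction, since pulling
*distant* markers together (or apart) by physical distance is a display
choice best left explicit.

The reference framework fixes a set of landmark markers shared across
datasets (defaults: DNA1, DNA2, Histone3, CD3, CD4, CD8a, CD20) evenly on
a unit circle, in fixed order — any fixed, documented arrangement serves
the purpose, which is that free markers' positions become comparable
across datasets. Each marker sends directed edges to the 5 markers with
the *smallest* mean k-NN distance from it. The edge budget and direction
semantics ("arrow ends at the closest markers") are the unambiguous
reading of the method's description; the neighbor count for the underlying
distances follows `knn_k` and is flag-controlled, since a single-nearest
variant is equally defensible for the dot-plot statistics.

# The phantom generator

`generate_phantom()` emulates exactly the inputs the toolkit consumes:
geometric anatomical regions (discs, annuli, bands, half-planes) painted
into a region map; cells as non-overlapping discs placed by rejection
sampling (1000 attempts per cell, then an error advising lower density);
per-cell marker positivity from the enrichment profile plus optional
pairwise coexpression; and marker images rendered as
`baseline + enrichment × positivity + clipped Gaussian noise`, rounded to
integer counts (IMC exports are 16-bit integers). Region footprints are
painted at the enrichment level outside cell discs so binarized masks
reproduce anatomy, while cell discs are painted from the cell's own
positivity so cell-level calls are honestly testable. The emitted cell
table is *recomputed* from the rendered images and mask by
`quantify_cells()`, never copied from ground truth. Defaults: 500 × 500 px
frames (the full ROI scale is configurable), baseline 5 counts, enrichment
~150 counts — comfortably below and above the 60-count threshold — and
noise off unless requested.

What the phantom does not model: ablation-plume spillover, isotope
impurity, hot pixels, segmentation errors, irregular cell shapes, or 3D
tissue. Passing tests therefore demonstrate algorithmic correctness on
idealized tissue geometry, not robustness to real IMC noise.

`generate_point_pattern()` plants a known nearest-neighbor offset: A
points sit on a jittered grid whose spacing (4× the offset scale)
guarantees each A's nearest B is its own planted partner, so the expected
nearest distance equals the offset by construction. Uniformly random A
points would not provide this guarantee at realistic densities — foreign
partners would often be nearer than the planted one — which is why the
generator uses a grid.

# Determinism and problem sizes

Every stochastic step takes an explicit integer seed; the pipeline derives
per-stage seeds from the global seed by a stable hash of the stage name,
and two runs of the same configuration produce byte-identical CSV outputs.
The test suite works at desk scale by choice: 120–500 px phantoms with
tens to hundreds of cells, point sets up to 500, 100 clustering seeds for
the recovery rate — sizes at which exhaustive and brute-force oracles
(full pairwise sorts, complete partition enumeration, small-step force
integration) are feasible alongside the implementation they check.

# Known limitations

* Pearson correlation and the KS test assume large cell counts; no exact
  small-sample alternatives are wired in.
* k-NN search is exact brute force — fine for desk-scale and single-ROI
  cell counts (10³–10⁵ query points), but a spatial index would be needed
  for pooled multi-ROI point sets in the millions.
* The anatomy clustering loads the full `n_markers × n_pixels` matrix;
  use the stride option for full-resolution multi-ROI batches.
* Peak matching is directional for non-singleton peak sets (a → b nearest
  matching), so `peak_distance(a, b)` and `peak_distance(b, a)` can
  differ when peak counts differ.
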