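# spatialmux

Spatial analysis of highly multiplexed tissue protein images — imaging
mass cytometry (IMC) and similar modalities that produce one intensity
image per protein marker (~20–40 channels, ~1 µm/pixel) plus a cell
segmentation mask. The package is for computational biologists who need to
go beyond per-cell expression tables: it links bottom-up single-cell
statistics to top-down tissue anatomy and measures how marker-positive
cell populations are arranged in physical space.

## What it computes

**Bottom-up (single cells).** Per-cell mean intensities and centroids from
a label mask (`quantify_cells`); positivity calls at a strict intensity
threshold; *percentage counts* (cells positive for a marker / cells
positive for ≥ 1 marker); Pearson correlations between markers with the
Fisher Z comparison of two conditions,

  z = (atanh(r₁) − atanh(r₂)) / √(1/(n₁−3) + 1/(n₂−3)),

and two-sample Kolmogorov–Smirnov tests for distribution shifts.

**Top-down (anatomy).** Marker masks binarized at a shared threshold
(default 60 counts, strict `>`); *area ratios* (positive pixels / total
pixels); k-means over the `n_markers × n_pixels` matrix of flattened masks
to group markers into anatomical clusters; cluster mean images and
rainbow-tinted overlay composites (2nd–98th percentile rescaling).

**Spatial structure.** Mean k-nearest-neighbor distances between
marker-positive cell sets (default k = 10, directed, self-pairs excluded);
intra-/inter-cluster distance summaries; nearest-neighbor proximity maps
with 20-bin distance histograms and the fraction of distances below 30 µm;
Gaussian-smoothed topographic height maps with peak detection and
inter-marker peak distances; spring-layout network graphs (node size =
area ratio, edge color = normalized distance) including a fixed-landmark
reference framework that pins shared markers (DNA1, DNA2, Histone3, CD3,
CD4, CD8a, CD20) on a circle so healthy and diseased datasets can be
compared in one frame.

**Synthetic phantoms.** `generate_phantom()` renders image stacks, label
masks and cell tables with planted regions, enrichment, coexpression and
noise — with ground truth — so every stage is testable without real data;
`generate_point_pattern()` plants known nearest-neighbor offsets.

## Worked example

A two-compartment phantom: CD3/CD4 enriched in a lymphoid-follicle disc,
CD68/Granzyme B in a crypt-like disc.

```r
library(spatialmux)

spec <- phantom_spec(
  image_size = c(300, 300),
  regions = list(region_disc(1, c(90, 90), 65),
                 region_disc(2, c(210, 210), 65)),
  marker_profiles = list(
    CD3       = list(baseline = 5, enrichment = c("1" = 150)),
    CD4       = list(baseline = 5, enrichment = c("1" = 140)),
    CD68      = list(baseline = 5, enrichment = c("2" = 150)),
    GranzymeB = list(baseline = 5, enrichment = c("2" = 140))),
  cell_density = 15, cell_radius_px = 3, seed = 11)
phantom <- generate_phantom(spec)
#> <tissue_phantom> 300 x 300 px, 4 markers, 40 cells, 2 regions

masks <- binarize_stack(phantom$stack, threshold = 60)
round(sapply(masks$masks, area_ratio), 3)
#>       CD3       CD4      CD68 GranzymeB
#>     0.148     0.148     0.148     0.148

cluster_markers_kmeans(masks, k = 2, seed = 1)
#> <cluster_assignment> 4 markers in 2 clusters (inertia 0)
#>   cluster 1: CD3, CD4
#>   cluster 2: CD68, GranzymeB

pts <- points_by_marker(phantom$cells)
round(marker_pair_distance_matrix(pts, k = 10), 1)
#>             CD3   CD4  CD68 GranzymeB
#> CD3        40.7  34.2 145.2     145.2
#> CD4        34.2  40.7 145.2     145.2
#> CD68      148.6 148.6  39.0      33.2
#> GranzymeB 148.6 148.6  33.2      39.0
```

Each disc covers ~14.8 % of the frame (area ratio 0.148); k-means on the
binarized masks recovers the planted marker grouping exactly (inertia 0:
same-region masks are identical); and the k-NN matrix separates
within-region distances (~35–40 µm, the spacing of cells inside one disc)
from cross-region distances (~145 µm, the gap between the discs).

Comparing two published-scale correlation coefficients between conditions:

```r
compare_correlations_fisher(0.24448, 56421, 0.57199, 56421)
#> $z_statistic
#> [1] -67.34038
#> $two_sided_p
#> [1] 0
```

A difference of |z| ≈ 67 between r = 0.24 and r = 0.57 at n = 56,421 cells
per condition is overwhelming evidence (p < 0.001) that the marker pair is
more strongly coupled in the second condition.

## Command line

```sh
inst/scripts/spatialmux run --config cfg.yaml --out out/   # all stages
inst/scripts/spatialmux anatomy --out out/                 # one stage
```

Stages: simulate, quantify, stats, anatomy, distances, proximity,
topography, network. A JSON manifest records the config, seed, output
digests and per-stage wall time; the same config and seed reproduce every
CSV byte for byte.

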