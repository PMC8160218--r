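Package: spatialmux
Title: Spatial Analysis of Highly Multiplexed Tissue Protein Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-cell and anatomical spatial analysis for highly
    multiplexed tissue protein images such as imaging mass cytometry
    (IMC) regions of interest. Reads per-marker intensity images,
    segmentation label masks and single-cell expression tables;
    quantifies per-cell mean intensities, marker positivity, percentage
    counts and correlation statistics (with Fisher Z comparison of
    correlations and two-sample Kolmogorov-Smirnov tests); discovers
    anatomical regions by k-means clustering of binarized marker masks;
    computes k-nearest-neighbor distances between marker-positive cell
    sets, intra-/inter-cluster distance summaries, nearest-neighbor
    proximity maps and histograms; builds topographic (smoothed
    intensity) maps with peak detection and inter-marker peak distances;
    and lays out spatial network graphs, including a fixed-landmark
    reference framework for cross-condition comparison. A synthetic
    tissue-phantom generator with planted ground truth supports
    end-to-end testing without real acquisitions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
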