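## Per-cell nearest-neighbor link maps between a marker pair, their distance
## histograms, and the all-pairs average-proximity heatmap.

#' Nearest-neighbor links between two marker cell sets
#'
#' Connects each origin cell to its single nearest destination cell (ties
#' broken by lowest destination index, so the output is deterministic).
#' Exactly one link per origin cell.
#'
#' @param origin,destination [point_set()]s; destination non-empty.
#' @return A list of class `proximity_links`: `marker_pair`, `links`
#'   (data.frame `origin_index`, `destination_index`, `distance_um`; indices
#'   are 1-based rows of the point sets), and empty histogram fields until
#'   [proximity_histogram()] fills them.
#' @export
nearest_links <- function(origin, destination) {
  if (nrow(origin$centroids) == 0)
    sm_stop(paste0("origin point set '", origin$marker_name, "' is empty"),
            "sm_empty_error")
  if (nrow(destination$centroids) == 0)
    sm_stop(paste0("destination point set '", destination$marker_name,
                   "' is empty"), "sm_empty_error")
  D <- pairwise_dist_px(origin$centroids, destination$centroids)
  j <- apply(D, 1, which.min)              # which.min takes the lowest index on ties
  d <- D[cbind(seq_len(nrow(D)), j)] * origin$pixel_size_um
  structure(list(marker_pair = c(origin$marker_name, destination$marker_name),
                 links = data.frame(origin_index = seq_len(nrow(D)),
                                    destination_index = j,
                                    distance_um = d),
                 bin_edges = NULL, proportions = NULL),
            class = "proximity_links")
}

#' @export
print.proximity_links <- function(x, ...) {
  cat(sprintf("<proximity_links> %s -> %s: %d links, mean %.3f um\n",
              x$marker_pair[1], x$marker_pair[2], nrow(x$links),
              mean(x$links$distance_um)))
  invisible(x)
}

#' Histogram of nearest-neighbor link distances
#'
#' Equal-width bins spanning `[0, max distance]`; values on bin boundaries
#' fall in the lower bin except 0 (right-closed bins including the lowest
#' edge), and proportions are counts over the number of links. When all
#' distances are zero a single bin at 0 is used.
#'
#' @param links a `proximity_links` from [nearest_links()].
#' @param bins number of bins (default 20).
#' @return The `proximity_links` with `bin_edges` (`bins + 1` values) and
#'   `proportions` (summing to 1) filled in.
#' @export
proximity_histogram <- function(links, bins = 20) {
  if (!inherits(links, "proximity_links"))
    sm_stop("'links' must come from nearest_links()")
  if (bins < 1) sm_stop("'bins' must be >= 1", "sm_argument_error")
  d <- links$links$distance_um
  mx <- max(d)
  if (mx == 0) {
    links$bin_edges <- c(0, 0)
    links$proportions <- 1
    return(links)
  }
  edges <- seq(0, mx, length.out = bins + 1)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE,
                           right = TRUE, include.lowest = TRUE)$counts
  links$bin_edges <- edges
  links$proportions <- counts / length(d)
  links
}

#' All-pairs average spatial proximity heatmap
#'
#' Entry `(i, j)` is the mean over marker-i cells of the mean distance to
#' their k nearest marker-j cells; the diagonal is computed with
#' self-exclusion. Shares its implementation with
#' [marker_pair_distance_matrix()].
#'
#' @param cells_by_marker named list of [point_set()]s.
#' @param k neighbor count (default 1 = single nearest neighbor).
#' @return A square numeric matrix of mean distances in micrometers.
#' @export
average_proximity_heatmap <- function(cells_by_marker, k = 1) {
  marker_pair_distance_matrix(cells_by_marker, k = k)
}
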