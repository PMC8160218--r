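## k-NN distance machinery between marker-positive cell sets: pairwise mean
## distance matrices, intra-/inter-cluster summaries and the below-cutoff
## proximity fraction.

#' Point set of marker-positive cell centroids
#'
#' @param marker_name marker the cells are positive for.
#' @param centroids two-column matrix of `(row, col)` 0-based pixel
#'   coordinates; may have zero rows.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A list of class `point_set`.
#' @export
point_set <- function(marker_name, centroids, pixel_size_um = 1) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) > 0 && ncol(centroids) != 2)
    sm_stop("'centroids' must have two columns (row, col)", "sm_format_error")
  if (nrow(centroids) > 0 && (anyNA(centroids) || any(!is.finite(centroids))))
    sm_stop("centroids must be finite", "sm_format_error")
  structure(list(marker_name = marker_name, centroids = centroids,
                 pixel_size_um = pixel_size_um),
            class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("<point_set> %s: %d cells @ %g um/px\n",
              x$marker_name, nrow(x$centroids), x$pixel_size_um))
  invisible(x)
}

#' Split a cell table into per-marker positive point sets
#'
#' Cells enter a marker's point set through the positivity call: the point
#' set of marker m holds the centroids of all cells whose mean intensity
#' exceeds m's threshold.
#'
#' @param cells a [cell_table()].
#' @param config an [analysis_config()] supplying thresholds.
#' @return A named list of [point_set()]s, one per marker.
#' @export
points_by_marker <- function(cells, config = analysis_config()) {
  pos <- call_positivity(cells, config)
  mk <- attr(cells, "markers")
  ps <- attr(cells, "pixel_size_um")
  stats::setNames(lapply(mk, function(m) {
    keep <- pos$calls[, m]
    point_set(m, cbind(cells$centroid_row[keep], cells$centroid_col[keep]), ps)
  }), mk)
}

# Pairwise Euclidean distances in pixels, query rows x reference cols.
pairwise_dist_px <- function(q, r) {
  d2 <- outer(q[, 1], r[, 1], "-")^2 + outer(q[, 2], r[, 2], "-")^2
  sqrt(pmax(d2, 0))
}

# Per-query sorted distances to the k nearest reference points (um).
# When self_exclude, entry j == i of row i is dropped (same-marker queries).
knn_dists_um <- function(query, reference, k, self_exclude = NULL) {
  if (is.null(self_exclude))
    self_exclude <- identical(query$marker_name, reference$marker_name) &&
      isTRUE(all.equal(query$centroids, reference$centroids,
                       check.attributes = FALSE))
  nq <- nrow(query$centroids); nr <- nrow(reference$centroids)
  if (nq == 0)
    sm_stop(paste0("point set for marker '", query$marker_name, "' is empty"),
            "sm_empty_error")
  if (nr == 0)
    sm_stop(paste0("point set for marker '", reference$marker_name, "' is empty"),
            "sm_empty_error")
  D <- pairwise_dist_px(query$centroids, reference$centroids)
  if (self_exclude) {
    if (nr <= 1)
      sm_stop("self-distance needs at least 2 cells", "sm_empty_error")
    diag(D) <- Inf
  }
  avail <- nr - as.integer(self_exclude)
  k_used <- min(k, avail)
  out <- matrix(0, nq, k_used)
  for (i in seq_len(nq)) {
    row <- D[i, ]
    out[i, ] <- sort.int(row, partial = seq_len(k_used))[seq_len(k_used)]
  }
  list(dists_um = out * query$pixel_size_um, k_used = k_used)
}

#' Mean k-nearest-neighbor distance between two marker cell sets
#'
#' For each query cell, the Euclidean distances to its `k_used` nearest
#' reference cells (exact self-pairs excluded when query and reference are
#' the same marker); the summary is the mean over all query cells and all
#' neighbors, in micrometers. `k_used` clamps to the reference set size.
#'
#' @param query,reference [point_set()]s; both non-empty.
#' @param k neighbor count (default 10).
#' @return A list of class `distance_summary` with `marker_pair`, `k_used`,
#'   `mean_knn_distance_um`, `n_query_cells`.
#' @export
knn_mean_distance <- function(query, reference, k = 10) {
  kd <- knn_dists_um(query, reference, k)
  structure(list(marker_pair = c(query$marker_name, reference$marker_name),
                 k_used = kd$k_used,
                 mean_knn_distance_um = mean(kd$dists_um),
                 n_query_cells = nrow(query$centroids)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> %s -> %s: mean %.3f um (k = %d, n = %d)\n",
              x$marker_pair[1], x$marker_pair[2], x$mean_knn_distance_um,
              x$k_used, x$n_query_cells))
  invisible(x)
}

#' Pairwise mean k-NN distance matrix across markers
#'
#' Entry `(i, j)` is the mean k-NN distance from marker i's cells to marker
#' j's cells ([knn_mean_distance()]); generally asymmetric. Empty markers
#' yield `NA` rows/columns, not zeros.
#'
#' @param cells_by_marker named list of [point_set()]s (see
#'   [points_by_marker()]).
#' @param k neighbor count.
#' @return A square numeric matrix with marker dimnames.
#' @export
marker_pair_distance_matrix <- function(cells_by_marker, k = 10) {
  mk <- names(cells_by_marker)
  nonempty <- vapply(cells_by_marker, function(p) nrow(p$centroids) > 0, logical(1))
  if (sum(nonempty) == 0)
    sm_stop("all marker point sets are empty", "sm_empty_error")
  if (sum(nonempty) < 2)
    sm_stop("need at least 2 non-empty markers", "sm_empty_error")
  M <- matrix(NA_real_, length(mk), length(mk), dimnames = list(mk, mk))
  for (i in seq_along(mk)) for (j in seq_along(mk)) {
    if (!nonempty[i] || !nonempty[j]) next
    if (i == j && nrow(cells_by_marker[[i]]$centroids) < 2) next
    M[i, j] <- knn_mean_distance(cells_by_marker[[i]], cells_by_marker[[j]],
                                 k)$mean_knn_distance_um
  }
  M
}

#' Intra-cluster marker-pair distances
#'
#' Edge list of marker pairs that share an anatomical cluster; each edge
#' weight is the mean of the two directed matrix entries.
#'
#' @param matrix square distance matrix from
#'   [marker_pair_distance_matrix()].
#' @param assignment a `cluster_assignment` covering all matrix markers.
#' @return A data.frame with columns `m_i`, `m_j`, `cluster`, `distance_um`.
#' @export
intra_cluster_distances <- function(matrix, assignment) {
  mk <- rownames(matrix)
  missing <- setdiff(mk, names(assignment))
  if (length(missing))
    sm_stop(paste0("assignment missing marker(s): ", paste(missing, collapse = ", ")),
            "sm_argument_error")
  out <- data.frame(m_i = character(0), m_j = character(0),
                    cluster = integer(0), distance_um = numeric(0))
  if (length(mk) < 2) return(out)
  for (i in seq_along(mk)) for (j in seq_along(mk)) {
    if (j <= i) next
    if (assignment[[mk[i]]] != assignment[[mk[j]]]) next
    out <- rbind(out, data.frame(m_i = mk[i], m_j = mk[j],
                                 cluster = assignment[[mk[i]]],
                                 distance_um = mean(c(matrix[i, j], matrix[j, i]))))
  }
  rownames(out) <- NULL
  out
}

#' Inter-cluster mean distance
#'
#' Mean of the directed matrix entries over all marker pairs drawn from two
#' distinct clusters, both directions included.
#'
#' @param matrix square distance matrix from
#'   [marker_pair_distance_matrix()].
#' @param assignment a `cluster_assignment`.
#' @param c1,c2 distinct cluster ids.
#' @return Mean distance in micrometers.
#' @export
inter_cluster_distance <- function(matrix, assignment, c1, c2) {
  if (c1 == c2) sm_stop("'c1' and 'c2' must be distinct clusters", "sm_argument_error")
  mk <- rownames(matrix)
  a <- intersect(mk, names(assignment)[assignment == c1])
  b <- intersect(mk, names(assignment)[assignment == c2])
  if (length(a) == 0 || length(b) == 0)
    sm_stop("unknown or empty cluster id", "sm_argument_error")
  vals <- c(matrix[a, b, drop = FALSE], matrix[b, a, drop = FALSE])
  mean(vals, na.rm = TRUE)
}

#' Nearest-neighbor proximity fraction
#'
#' Per-query-cell single nearest-neighbor (`k = 1`) distances to the
#' reference set; returns their mean and the share strictly below the
#' cutoff (default 30 micrometers).
#'
#' @param query,reference [point_set()]s; both non-empty.
#' @param cutoff_um distance cutoff in micrometers.
#' @return A list with `mean_nn_distance_um` and `fraction` in `[0, 1]`.
#' @export
proximity_fraction <- function(query, reference, cutoff_um = 30) {
  if (cutoff_um <= 0) sm_stop("'cutoff_um' must be > 0", "sm_argument_error")
  kd <- knn_dists_um(query, reference, 1)
  d <- kd$dists_um[, 1]
  list(mean_nn_distance_um = mean(d), fraction = mean(d < cutoff_um))
}
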