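## Spatial network graphs: intra-/inter-cluster maps, the fixed-landmark
## reference framework, the force-directed layout that drives them, and the
## dot-plot summary statistics for cross-condition comparison.

normalize_weights <- function(w) {
  rng <- range(w)
  if (!is.finite(rng[1]) || rng[2] <= rng[1]) return(rep(0, length(w)))
  (w - rng[1]) / (rng[2] - rng[1])
}

#' Build the intra- or inter-cluster spatial network graph
#'
#' Intra mode: marker nodes (size = area ratio, colored by cluster) with an
#' undirected edge for every same-cluster marker pair, weighted by the mean
#' of the two directed k-NN distances. Inter mode: one node per anatomical
#' cluster (size = mean member area ratio) with one weighted edge per
#' cluster pair ([inter_cluster_distance()]), plus marker nodes tied to
#' their cluster node by unweighted membership edges. In both modes
#' `normalized_weight = (w - min) / (max - min)` over the weighted edge set
#' (0 when fewer than two distinct weights exist), so red-to-blue edge
#' colormaps can read relative closeness directly.
#'
#' @param matrix square distance matrix from
#'   [marker_pair_distance_matrix()].
#' @param assignment a `cluster_assignment`.
#' @param area_ratios named per-marker area ratios (see [area_ratios()]).
#' @param mode `"intra"` or `"inter"`.
#' @return An igraph graph with node attributes `size`, `cluster`, `fixed`
#'   and edge attributes `weight_um`, `normalized_weight`, `kind`.
#' @export
build_cluster_graph <- function(matrix, assignment, area_ratios,
                                mode = c("intra", "inter")) {
  mode <- match.arg(mode)
  mk <- rownames(matrix)
  missing <- setdiff(mk, names(assignment))
  if (length(missing))
    sm_stop(paste0("assignment missing marker(s): ", paste(missing, collapse = ", ")),
            "sm_argument_error")
  missing <- setdiff(mk, names(area_ratios))
  if (length(missing))
    sm_stop(paste0("area ratios missing marker(s): ", paste(missing, collapse = ", ")),
            "sm_argument_error")
  if (mode == "intra") {
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, length(mk), name = mk,
                              size = unname(area_ratios[mk]),
                              cluster = unname(assignment[mk]),
                              fixed = FALSE)
    edges <- intra_cluster_distances(matrix, assignment)
    if (nrow(edges)) {
      g <- igraph::add_edges(g, as.vector(rbind(edges$m_i, edges$m_j)),
                             weight_um = edges$distance_um, kind = "distance")
      igraph::E(g)$normalized_weight <- normalize_weights(edges$distance_um)
    }
    return(g)
  }
  ## inter mode
  K <- attr(assignment, "K")
  clusters <- sort(unique(unname(assignment[mk])))
  cl_names <- paste0("cluster_", clusters)
  cl_size <- vapply(clusters, function(cl)
    mean(area_ratios[intersect(mk, names(assignment)[assignment == cl])]),
    numeric(1))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(clusters), name = cl_names,
                            size = cl_size, cluster = clusters, fixed = FALSE)
  g <- igraph::add_vertices(g, length(mk), name = mk,
                            size = unname(area_ratios[mk]),
                            cluster = unname(assignment[mk]), fixed = FALSE)
  w <- numeric(0)
  if (length(clusters) >= 2) {
    pairs <- utils::combn(seq_along(clusters), 2)
    for (p in seq_len(ncol(pairs))) {
      c1 <- clusters[pairs[1, p]]; c2 <- clusters[pairs[2, p]]
      d <- inter_cluster_distance(matrix, assignment, c1, c2)
      g <- igraph::add_edges(g, c(paste0("cluster_", c1), paste0("cluster_", c2)),
                             weight_um = d, kind = "distance")
      w <- c(w, d)
    }
  }
  for (m in mk)
    g <- igraph::add_edges(g, c(m, paste0("cluster_", assignment[[m]])),
                           weight_um = NA_real_, kind = "membership")
  nw <- rep(NA_real_, igraph::ecount(g))
  is_d <- igraph::E(g)$kind == "distance"
  nw[is_d] <- normalize_weights(w)
  igraph::E(g)$normalized_weight <- nw
  g
}

#' Force-directed spring layout with fixed landmark nodes
#'
#' Fruchterman-Reingold layout in the networkx parameterization: `k` is the
#' optimal pairwise distance, repulsion `k^2/d`, attraction `w d^2/k` along
#' edges, with linear cooling from an initial temperature of one tenth of
#' the starting frame over `iterations` steps. Nodes listed in `fixed` never
#' move (exact equality with their input positions); free nodes start from
#' seeded uniform positions in the unit square. Positions are returned in
#' force-model units (pairwise separations equilibrate near `k`), with no
#' cosmetic rescaling, so fixed-landmark frames stay comparable across
#' datasets.
#'
#' @param graph an igraph graph.
#' @param k optimal node distance; defaults to `1/sqrt(n)`.
#' @param iterations number of layout iterations.
#' @param seed integer RNG seed for the initial positions.
#' @param fixed character vector of node names to clamp; each must have a
#'   row in `initial`.
#' @param initial optional numeric matrix of starting positions with node
#'   rownames (required for fixed nodes).
#' @param weights optional edge weights for the attractive force; defaults
#'   to 1 for every edge.
#' @return An `n x 2` numeric matrix of positions with node rownames.
#' @export
layout_spring <- function(graph, k = NULL, iterations = 50, seed = 1L,
                          fixed = character(0), initial = NULL, weights = NULL) {
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(graph)))
  n <- length(nodes)
  if (n == 0) sm_stop("graph has no nodes", "sm_argument_error")
  unknown <- setdiff(fixed, nodes)
  if (length(unknown))
    sm_stop(paste0("unknown fixed node(s): ", paste(unknown, collapse = ", ")),
            "sm_argument_error")
  if (length(fixed) && (is.null(initial) || !all(fixed %in% rownames(initial))))
    sm_stop("fixed nodes require rows in 'initial'", "sm_argument_error")
  if (is.null(k)) k <- 1 / sqrt(n)
  set.seed(seed)
  pos <- matrix(stats::runif(2 * n), n, 2, dimnames = list(nodes, NULL))
  if (!is.null(initial)) {
    common <- intersect(rownames(initial), nodes)
    pos[common, ] <- as.matrix(initial[common, , drop = FALSE])
  }
  free <- !(nodes %in% fixed)
  el <- igraph::as_edgelist(graph, names = TRUE)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(el)) {
    w <- if (is.null(weights)) rep(1, nrow(el)) else weights
    for (e in seq_len(nrow(el))) {
      A[el[e, 1], el[e, 2]] <- A[el[e, 1], el[e, 2]] + w[e]
      if (!igraph::is_directed(graph))
        A[el[e, 2], el[e, 1]] <- A[el[e, 2], el[e, 1]] + w[e]
      else
        A[el[e, 2], el[e, 1]] <- A[el[e, 2], el[e, 1]] + w[e]
    }
  }
  t_cool <- max(apply(pos, 2, function(x) diff(range(x))), 1e-3) * 0.1
  dt <- t_cool / (iterations + 1)
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1], pos[, 1], "-")
    dy <- outer(pos[, 2], pos[, 2], "-")
    dist <- sqrt(dx^2 + dy^2)
    dist[dist < 0.01] <- 0.01
    coef <- k^2 / dist^2 - A * dist / k
    disp_x <- rowSums(dx * coef) - diag(dx * coef)  # exclude self term
    disp_y <- rowSums(dy * coef) - diag(dy * coef)
    len <- sqrt(disp_x^2 + disp_y^2)
    len[len < 0.01] <- 0.1
    step <- t_cool / len
    pos[free, 1] <- pos[free, 1] + (disp_x * step)[free]
    pos[free, 2] <- pos[free, 2] + (disp_y * step)[free]
    t_cool <- t_cool - dt
  }
  pos
}

#' Landmark positions on the unit circle
#'
#' Evenly spaced positions, in the given (fixed) marker order, used to
#' pre-position landmark nodes of the reference framework.
#'
#' @param landmarks character vector of landmark marker names.
#' @param radius circle radius.
#' @return A matrix of `(x, y)` positions with landmark rownames.
#' @export
landmark_circle_positions <- function(landmarks, radius = 1) {
  n <- length(landmarks)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  matrix(c(radius * cos(theta), radius * sin(theta)), n, 2,
         dimnames = list(landmarks, NULL))
}

#' Build the fixed-landmark spatial reference graph
#'
#' Directed graph over all markers: each marker sends edges to the markers
#' with the smallest mean k-NN distance from it (its closest markers;
#' `reference_edges_per_marker` of them, clamped to the available marker
#' count). Landmark markers are flagged fixed and pre-positioned evenly on
#' a unit circle so layouts of different datasets share a common frame;
#' node size is the marker's area ratio.
#'
#' @param matrix square distance matrix from
#'   [marker_pair_distance_matrix()].
#' @param area_ratios named per-marker area ratios.
#' @param config an [analysis_config()] supplying `landmark_markers` and
#'   `reference_edges_per_marker`.
#' @return A directed igraph graph with node attributes `size`, `fixed`,
#'   `x`, `y` (landmark positions; `NA` for free nodes) and edge attributes
#'   `weight_um`, `normalized_weight`.
#' @export
build_reference_graph <- function(matrix, area_ratios, config = analysis_config()) {
  mk <- rownames(matrix)
  landmarks <- intersect(config$landmark_markers, mk)
  missing <- setdiff(config$landmark_markers, mk)
  if (length(missing))
    sm_stop(paste0("landmark marker(s) absent from the data: ",
                   paste(missing, collapse = ", ")), "sm_argument_error")
  lpos <- landmark_circle_positions(landmarks)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(mk), name = mk,
                            size = unname(area_ratios[mk]),
                            fixed = mk %in% landmarks,
                            x = ifelse(mk %in% landmarks,
                                       lpos[match(mk, landmarks), 1], NA_real_),
                            y = ifelse(mk %in% landmarks,
                                       lpos[match(mk, landmarks), 2], NA_real_))
  n_out <- min(config$reference_edges_per_marker, length(mk) - 1)
  w <- numeric(0)
  for (m in mk) {
    d <- matrix[m, setdiff(mk, m)]
    d <- d[!is.na(d)]
    if (length(d) == 0) next
    targets <- names(sort(d))[seq_len(min(n_out, length(d)))]
    for (tg in targets) {
      g <- igraph::add_edges(g, c(m, tg), weight_um = matrix[m, tg])
      w <- c(w, matrix[m, tg])
    }
  }
  if (length(w)) igraph::E(g)$normalized_weight <- normalize_weights(w)
  g
}

#' Lay out a reference graph with landmarks held fixed
#'
#' Convenience wrapper running [layout_spring()] with the reference-frame
#' parameters (`spring_k_reference`, `spring_iter_reference`) and the
#' landmark circle positions clamped.
#'
#' @param graph a reference graph from [build_reference_graph()].
#' @param config an [analysis_config()].
#' @param seed integer RNG seed.
#' @return An `n x 2` position matrix with node rownames.
#' @export
layout_reference <- function(graph, config = analysis_config(),
                             seed = config$rng_seed) {
  fixed <- igraph::V(graph)$name[igraph::V(graph)$fixed]
  init <- cbind(igraph::V(graph)$x, igraph::V(graph)$y)
  rownames(init) <- igraph::V(graph)$name
  init <- init[fixed, , drop = FALSE]
  layout_spring(graph, k = config$spring_k_reference,
                iterations = config$spring_iter_reference, seed = seed,
                fixed = fixed, initial = init)
}

#' Write a spatial graph to GraphML or JSON
#'
#' GraphML keeps all node/edge attributes; the JSON mirror holds `nodes`
#' and `edges` arrays for web use.
#'
#' @param graph an igraph graph.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @param positions optional position matrix (node rownames) stored as
#'   `x`/`y` node attributes before writing.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(graph, path, format = c("graphml", "json"),
                                positions = NULL) {
  format <- match.arg(format)
  if (!is.null(positions)) {
    nm <- igraph::V(graph)$name
    igraph::V(graph)$x <- positions[nm, 1]
    igraph::V(graph)$y <- positions[nm, 2]
  }
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    vat <- as.data.frame(igraph::vertex_attr(graph), stringsAsFactors = FALSE)
    edf <- igraph::as_data_frame(graph, what = "edges")
    jsonlite::write_json(list(nodes = vat, edges = edf), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Dot-plot summary across datasets
#'
#' For each dataset (condition/ROI): per-marker normalized expression (mean
#' single-cell intensity scaled by the dataset maximum, so the top marker is
#' 1), cell prevalence area (fraction of image pixels covered by the
#' marker's positive cells), and per marker pair the mean nearest-neighbor
#' cell-to-cell distance with the fraction below the cutoff.
#'
#' @param datasets named list; each element is a list with `cells` (a
#'   [cell_table()]) and `mask` (the dataset's [label_mask()]).
#' @param config an [analysis_config()] supplying thresholds and the
#'   proximity cutoff.
#' @return A list of class `dot_summary` with data.frames `expression`
#'   (dataset, marker, normalized_expression, cell_prevalence_area) and
#'   `pairwise` (dataset, m_i, m_j, mean_cell_distance_um,
#'   fraction_below_cutoff; `NA` rows where a marker has no positive cells).
#' @export
dot_summary <- function(datasets, config = analysis_config()) {
  if (length(datasets) == 0) sm_stop("'datasets' must be non-empty", "sm_argument_error")
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  expr <- NULL; pw <- NULL
  for (ds in names(datasets)) {
    cells <- datasets[[ds]]$cells
    mask <- datasets[[ds]]$mask
    if (!inherits(cells, "cell_table") || nrow(cells) == 0)
      sm_stop(paste0("dataset '", ds, "' has no cells"), "sm_empty_error")
    mk <- attr(cells, "markers")
    pos <- call_positivity(cells, config)
    means <- vapply(mk, function(m) mean(cells[[m]]), numeric(1))
    norm_expr <- means / max(means)
    prev <- vapply(mk, function(m) {
      ids <- cells$cell_id[pos$calls[, m]]
      if (length(ids) == 0 || is.null(mask)) return(0)
      mean(mask$labels %in% ids)
    }, numeric(1))
    expr <- rbind(expr, data.frame(dataset = ds, marker = mk,
                                   normalized_expression = unname(norm_expr),
                                   cell_prevalence_area = unname(prev)))
    pts <- points_by_marker(cells, config)
    for (i in seq_along(mk)) for (j in seq_along(mk)) {
      if (j <= i) next
      pi <- pts[[mk[i]]]; pj <- pts[[mk[j]]]
      if (nrow(pi$centroids) == 0 || nrow(pj$centroids) == 0) {
        pw <- rbind(pw, data.frame(dataset = ds, m_i = mk[i], m_j = mk[j],
                                   mean_cell_distance_um = NA_real_,
                                   fraction_below_cutoff = NA_real_))
      } else {
        pf <- proximity_fraction(pi, pj, config$proximity_cutoff_um)
        pw <- rbind(pw, data.frame(dataset = ds, m_i = mk[i], m_j = mk[j],
                                   mean_cell_distance_um = pf$mean_nn_distance_um,
                                   fraction_below_cutoff = pf$fraction))
      }
    }
  }
  rownames(expr) <- rownames(pw) <- NULL
  structure(list(expression = expr, pairwise = pw,
                 cutoff_um = config$proximity_cutoff_um),
            class = "dot_summary")
}

#' @export
print.dot_summary <- function(x, ...) {
  cat(sprintf("<dot_summary> %d dataset(s), cutoff %g um\n",
              length(unique(x$expression$dataset)), x$cutoff_um))
  print(utils::head(x$expression, 12))
  invisible(x)
}
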