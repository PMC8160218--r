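## Top-down anatomy: binarized marker masks, area ratios, k-means grouping
## of markers into anatomical clusters, cluster mean images and the combined
## color overlay.

#' Binarize a marker image
#'
#' `mask = intensity > threshold` (strict comparison; the threshold value
#' itself is excluded). The default threshold of 60 counts is the standard
#' setting for IMC-scale intensity images.
#'
#' @param img a [marker_image()] or numeric matrix.
#' @param threshold intensity threshold in counts, `>= 0`.
#' @return A logical matrix.
#' @export
binarize_marker <- function(img, threshold = 60) {
  if (threshold < 0) sm_stop("'threshold' must be >= 0", "sm_argument_error")
  px <- if (inherits(img, "marker_image")) img$pixels else as.matrix(img)
  px > threshold
}

#' Binarize every marker in a stack
#'
#' @param stack an [image_stack()].
#' @param threshold intensity threshold in counts.
#' @return A list of class `binary_mask_set`: per-marker logical grids plus
#'   `threshold_used`.
#' @export
binarize_stack <- function(stack, threshold = 60) {
  if (!inherits(stack, "image_stack")) sm_stop("'stack' must be an image_stack")
  masks <- lapply(stack$markers, binarize_marker, threshold = threshold)
  structure(list(masks = masks, threshold_used = threshold,
                 pixel_size_um = stack$pixel_size_um),
            class = "binary_mask_set")
}

#' Area ratio of a binary mask
#'
#' Fraction of image pixels where the marker's binarized expression mask is
#' positive: positive pixels divided by total pixels.
#'
#' @param mask logical matrix (or 0/1 numeric).
#' @return A number in `[0, 1]`.
#' @export
area_ratio <- function(mask) {
  mask <- as.matrix(mask)
  if (length(mask) == 0) sm_stop("'mask' must be non-empty", "sm_argument_error")
  mean(mask > 0)
}

#' Area ratios for all markers in a stack
#'
#' @param stack an [image_stack()].
#' @param threshold binarization threshold in counts.
#' @return A named numeric vector of per-marker area ratios.
#' @export
area_ratios <- function(stack, threshold = 60) {
  bm <- binarize_stack(stack, threshold)
  vapply(bm$masks, area_ratio, numeric(1))
}

#' Cluster markers into anatomical groups by k-means on binarized masks
#'
#' Markers are the observations and flattened mask pixels the features (an
#' `n_markers x n_pixels` 0/1 matrix): the clustering groups marker images
#' by the spread and shape of their expressed regions, so each cluster is a
#' proxy for an anatomical compartment. Lloyd's algorithm is run with
#' `n_init` random restarts and the lowest-inertia solution kept. Rows are
#' canonicalized by sorted marker name and initial centers are drawn from
#' the distinct mask patterns, so the result is invariant to marker order
#' and deterministic given the seed.
#'
#' @param masks a `binary_mask_set` from [binarize_stack()].
#' @param k number of clusters, `1 <= k <= n_markers`.
#' @param config an [analysis_config()] supplying `kmeans_n_init` and
#'   `kmeans_max_iter`.
#' @param seed integer RNG seed (default `config$rng_seed`).
#' @param stride optional integer downsampling stride applied to both axes
#'   before clustering (default 1 = exact full-resolution path).
#' @return A named integer vector (marker -> cluster id in `1..k`) of class
#'   `cluster_assignment`, with attributes `K`, `inertia` and `seed`.
#' @export
cluster_markers_kmeans <- function(masks, k = 6, config = analysis_config(),
                                   seed = config$rng_seed, stride = 1L) {
  if (!inherits(masks, "binary_mask_set"))
    sm_stop("'masks' must be a binary_mask_set")
  mk <- sort(names(masks$masks))
  if (k < 1 || k > length(mk))
    sm_stop(paste0("'k' must be between 1 and the number of markers (",
                   length(mk), ")"), "sm_argument_error")
  sub <- function(m) {
    if (stride > 1) m <- m[seq(1, nrow(m), by = stride),
                           seq(1, ncol(m), by = stride), drop = FALSE]
    as.numeric(m)
  }
  X <- t(vapply(mk, function(m) sub(masks$masks[[m]]),
                numeric(length(sub(masks$masks[[1]])))))
  set.seed(seed)
  ux <- unique(X)
  if (nrow(ux) < k)
    sm_stop(paste0("only ", nrow(ux), " distinct marker masks; cannot form ",
                   k, " clusters"), "sm_argument_error")
  best <- NULL
  for (i in seq_len(config$kmeans_n_init)) {
    centers <- ux[sample.int(nrow(ux), k), , drop = FALSE]
    emptied <- FALSE
    km <- withCallingHandlers(
      tryCatch(stats::kmeans(X, centers = centers,
                             iter.max = config$kmeans_max_iter,
                             algorithm = "Lloyd"),
               error = function(e) NULL),
      warning = function(w) {
        if (grepl("empty cluster", conditionMessage(w))) emptied <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (is.null(km) || emptied || length(unique(km$cluster)) < k) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best))
    sm_stop("k-means failed in every restart (degenerate masks?)", "sm_internal_error")
  structure(stats::setNames(as.integer(best$cluster), mk),
            K = as.integer(k), inertia = best$tot.withinss, seed = seed,
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d markers in %d clusters (inertia %.4g)\n",
              length(x), attr(x, "K"), attr(x, "inertia")))
  for (cl in seq_len(attr(x, "K")))
    cat(sprintf("  cluster %d: %s\n", cl,
                paste(names(x)[x == cl], collapse = ", ")))
  invisible(x)
}

#' Mean image of an anatomical cluster
#'
#' Pixel-wise mean of the raw intensity images of the cluster's member
#' markers.
#'
#' @param stack an [image_stack()].
#' @param assignment a `cluster_assignment`.
#' @param cluster_id cluster id in `1..K`.
#' @return A [marker_image()] named `cluster_<id>`.
#' @export
cluster_mean_image <- function(stack, assignment, cluster_id) {
  members <- names(assignment)[assignment == cluster_id]
  if (length(members) == 0)
    sm_stop(paste0("cluster ", cluster_id, " is empty or unknown"),
            "sm_argument_error")
  missing <- setdiff(members, marker_names(stack))
  if (length(missing))
    sm_stop(paste0("markers not in stack: ", paste(missing, collapse = ", ")),
            "sm_argument_error")
  acc <- Reduce(`+`, lapply(members, function(m) stack$markers[[m]]$pixels))
  marker_image(acc / length(members), paste0("cluster_", cluster_id),
               pixel_size_um = stack$pixel_size_um)
}

#' Percentile rescaling for display
#'
#' Linear map of the `[p_low, p_high]` percentile intensity range onto
#' `[0, 1]`, clipped outside. A degenerate range (equal percentiles, e.g. a
#' constant image) maps to all zeros.
#'
#' @param img a [marker_image()] or numeric matrix.
#' @param low_pct,high_pct percentile bounds (defaults 2 and 98).
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
percentile_rescale <- function(img, low_pct = 2, high_pct = 98) {
  if (low_pct >= high_pct || low_pct < 0 || high_pct > 100)
    sm_stop("percentiles must be strictly increasing within [0, 100]",
            "sm_argument_error")
  px <- if (inherits(img, "marker_image")) img$pixels else as.matrix(img)
  qs <- stats::quantile(px, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (qs[2] <= qs[1]) return(matrix(0, nrow(px), ncol(px)))
  pmin(pmax((px - qs[1]) / (qs[2] - qs[1]), 0), 1)
}

#' Combined anatomical-cluster overlay
#'
#' Each cluster's mean image is percentile-rescaled, tinted with an evenly
#' spaced rainbow hue, and the layers are combined by per-pixel channel
#' maximum so every region keeps its own hue.
#'
#' @param stack an [image_stack()].
#' @param assignment a `cluster_assignment`.
#' @param config an [analysis_config()] supplying the rescale percentiles.
#' @return A `rows x cols x 3` RGB array with values in `[0, 1]`, with
#'   attribute `cluster_colors` (hex color per cluster).
#' @export
compose_cluster_overlay <- function(stack, assignment, config = analysis_config()) {
  K <- attr(assignment, "K")
  if (is.null(K) || K < 1) sm_stop("'assignment' must be a cluster_assignment")
  dims <- stack_dim(stack)
  cols <- grDevices::rainbow(K, end = max(0.001, (K - 1) / K))
  comp <- array(0, c(dims[1], dims[2], 3))
  pcts <- config$rescale_percentiles
  for (cl in seq_len(K)) {
    scaled <- percentile_rescale(cluster_mean_image(stack, assignment, cl),
                                 pcts[1], pcts[2])
    rgbv <- grDevices::col2rgb(cols[cl])[, 1] / 255
    for (ch in 1:3)
      comp[, , ch] <- pmax(comp[, , ch], scaled * rgbv[ch])
  }
  attr(comp, "cluster_colors") <- cols
  comp
}
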