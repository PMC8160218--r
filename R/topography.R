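## Topographic maps of marker expression: RGB overlay composites, smoothed
## height grids with contour levels, peak detection and inter-marker peak
## distances.

#' Three-channel RGB overlay composite
#'
#' Each marker is percentile-rescaled (2nd-98th by default) into its
#' assigned color channel.
#'
#' @param imgs list of exactly three [marker_image()]s with equal
#'   dimensions.
#' @param channel_order character vector mapping the three images to
#'   channels, a permutation of `c("red", "green", "blue")`.
#' @param low_pct,high_pct rescale percentiles.
#' @return A `rows x cols x 3` RGB array in `[0, 1]` (R, G, B slices).
#' @export
overlay_composite <- function(imgs, channel_order = c("red", "green", "blue"),
                              low_pct = 2, high_pct = 98) {
  if (length(imgs) != 3) sm_stop("'imgs' must contain exactly 3 marker images")
  if (!setequal(channel_order, c("red", "green", "blue")) ||
      length(channel_order) != 3)
    sm_stop("'channel_order' must be a permutation of red, green, blue",
            "sm_argument_error")
  dims <- lapply(imgs, function(im) dim(im$pixels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    sm_stop("overlay images must share dimensions", "sm_dim_error")
  comp <- array(0, c(dims[[1]], 3))
  slot <- match(c("red", "green", "blue"), channel_order)
  for (ch in 1:3)
    comp[, , ch] <- percentile_rescale(imgs[[slot[ch]]], low_pct, high_pct)
  comp
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing with symmetric (reflect) padding, so border
# peaks are not dimmed and total mass is preserved away from hard edges.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  conv_rows <- function(m) {
    n <- nrow(m)
    rpad <- min(r, n)
    pad <- rbind(m[rev(seq_len(rpad)), , drop = FALSE], m,
                 m[n + 1 - seq_len(rpad), , drop = FALSE])
    if (rpad < r) {  # tiny images: extend by edge replication
      pad <- rbind(pad[rep(1, r - rpad), , drop = FALSE], pad,
                   pad[rep(nrow(pad), r - rpad), , drop = FALSE])
    }
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

#' Topographic height grid of a marker
#'
#' Gaussian smoothing of the raw intensity image (symmetric boundary
#' reflection) followed by strided downsampling; contour levels are evenly
#' spaced between the minimum and maximum height. A constant image yields
#' an empty (degenerate) level set.
#'
#' @param img a [marker_image()].
#' @param sigma_px Gaussian smoothing sigma in pixels (default 5; 0 keeps
#'   the raw intensities).
#' @param stride integer downsampling stride (default 4).
#' @param n_levels number of contour levels (default 10).
#' @return A list of class `topography_grid`: `marker_name`, `heights`
#'   (downsampled grid), `smoothing_sigma_px`, `downsample_stride`,
#'   `contour_levels` (strictly increasing), `pixel_size_um`.
#' @export
make_topography <- function(img, sigma_px = 5, stride = 4, n_levels = 10) {
  if (!inherits(img, "marker_image")) sm_stop("'img' must be a marker_image")
  if (sigma_px < 0) sm_stop("'sigma_px' must be >= 0", "sm_argument_error")
  if (stride < 1 || stride != round(stride))
    sm_stop("'stride' must be an integer >= 1", "sm_argument_error")
  if (n_levels < 1) sm_stop("'n_levels' must be >= 1", "sm_argument_error")
  h <- gaussian_smooth(img$pixels, sigma_px)
  if (stride > 1)
    h <- h[seq(1, nrow(h), by = stride), seq(1, ncol(h), by = stride),
           drop = FALSE]
  rng <- range(h)
  levels <- if (rng[2] > rng[1])
    seq(rng[1], rng[2], length.out = n_levels + 2)[seq_len(n_levels) + 1]
  else numeric(0)
  structure(list(marker_name = img$marker_name, heights = h,
                 smoothing_sigma_px = sigma_px,
                 downsample_stride = as.integer(stride),
                 contour_levels = levels,
                 pixel_size_um = img$pixel_size_um),
            class = "topography_grid")
}

#' @export
print.topography_grid <- function(x, ...) {
  cat(sprintf("<topography_grid> %s: %d x %d (stride %d, sigma %g px), %d levels\n",
              x$marker_name, nrow(x$heights), ncol(x$heights),
              x$downsample_stride, x$smoothing_sigma_px,
              length(x$contour_levels)))
  invisible(x)
}

#' Detect expression peaks in a topographic grid
#'
#' Local maxima of the smoothed height grid (strictly greater than all 8
#' neighbors) above `min_height`, kept greedily in descending height order
#' subject to a minimum pairwise separation. Peak coordinates are reported
#' on the original pixel grid (0-based), undoing the downsampling stride.
#'
#' @param grid a `topography_grid` from [make_topography()].
#' @param min_height minimum peak height (same units as the intensities).
#' @param min_separation_px minimum pairwise peak separation in original
#'   pixels (>= 1).
#' @return A list of class `peak_set`: `marker_name`, `peaks` (data.frame
#'   `row`, `col`, `height`, sorted by descending height), thresholds used,
#'   `pixel_size_um`. May be empty.
#' @export
find_peaks <- function(grid, min_height = 0, min_separation_px = 10) {
  if (!inherits(grid, "topography_grid"))
    sm_stop("'grid' must come from make_topography()")
  if (min_separation_px < 1)
    sm_stop("'min_separation_px' must be >= 1", "sm_argument_error")
  h <- grid$heights
  n <- nrow(h); m <- ncol(h)
  pad <- matrix(-Inf, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- h
  is_max <- matrix(TRUE, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (h > pad[2:(n + 1) + dr, 2:(m + 1) + dc])
  }
  cand <- which(is_max & h > min_height, arr.ind = TRUE)
  stride <- grid$downsample_stride
  peaks <- data.frame(row = numeric(0), col = numeric(0), height = numeric(0))
  if (nrow(cand)) {
    hts <- h[cand]
    ord <- order(hts, decreasing = TRUE)
    kept <- matrix(numeric(0), 0, 2)
    kept_h <- numeric(0)
    for (i in ord) {
      p <- (cand[i, ] - 1) * stride          # back to 0-based original pixels
      if (nrow(kept) == 0 ||
          all((kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2 >= min_separation_px^2)) {
        kept <- rbind(kept, p)
        kept_h <- c(kept_h, hts[i])
      }
    }
    peaks <- data.frame(row = kept[, 1], col = kept[, 2], height = kept_h)
    rownames(peaks) <- NULL
  }
  structure(list(marker_name = grid$marker_name, peaks = peaks,
                 min_peak_height = min_height,
                 min_separation_px = min_separation_px,
                 pixel_size_um = grid$pixel_size_um),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %s: %d peaks\n", x$marker_name, nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' Mean distance between two markers' expression peaks
#'
#' Each peak of the first marker is matched to its nearest peak of the
#' second; the result is the mean matched distance in micrometers. This is
#' the quantitative reading of "distance between the peaks" of two layered
#' markers (e.g. an epithelial marker ringing a crypt versus a layered
#' surface marker).
#'
#' @param a,b `peak_set`s from [find_peaks()]; both non-empty.
#' @return Mean nearest-match distance in micrometers.
#' @export
peak_distance <- function(a, b) {
  if (!inherits(a, "peak_set") || !inherits(b, "peak_set"))
    sm_stop("'a' and 'b' must be peak_set objects")
  if (nrow(a$peaks) == 0 || nrow(b$peaks) == 0)
    sm_stop("peak sets must be non-empty", "sm_empty_error")
  D <- pairwise_dist_px(as.matrix(a$peaks[, c("row", "col")]),
                        as.matrix(b$peaks[, c("row", "col")]))
  mean(apply(D, 1, min)) * a$pixel_size_um
}
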