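## Bottom-up single-cell quantification: per-cell mean intensities from a
## label mask, positivity calls, percentage counts, and the correlation /
## distribution statistics used to compare conditions.

#' Quantify per-cell mean intensities from an image stack and label mask
#'
#' For every labeled cell: centroid = unweighted mean of member pixel
#' coordinates (0-based, row-major), and per-marker mean intensity = mean
#' over member pixels — the MeasureObjectIntensity convention. Cells are
#' ordered by ascending label; labels are preserved, never renumbered.
#'
#' @param stack an [image_stack()].
#' @param mask a [label_mask()] with the same dimensions.
#' @return A [cell_table()]; empty (0 rows) for an empty mask.
#' @export
quantify_cells <- function(stack, mask) {
  if (!inherits(stack, "image_stack")) sm_stop("'stack' must be an image_stack")
  if (!inherits(mask, "label_mask")) sm_stop("'mask' must be a label_mask")
  dims <- stack_dim(stack)
  if (!identical(dims, dim(mask$labels)))
    sm_stop("stack and mask dimensions differ", "sm_dim_error")
  idx <- which(mask$labels > 0L)
  mk <- marker_names(stack)
  if (length(idx) == 0L) {
    df <- data.frame(cell_id = integer(0), centroid_row = numeric(0),
                     centroid_col = numeric(0))
    for (m in mk) df[[m]] <- numeric(0)
    return(cell_table(df, markers = mk, pixel_size_um = stack$pixel_size_um))
  }
  labs <- mask$labels[idx]
  f <- factor(labs)
  ids <- as.integer(levels(f))
  npix <- as.vector(table(f))
  r0 <- (idx - 1) %% dims[1]          # 0-based row (column-major storage)
  c0 <- (idx - 1) %/% dims[1]         # 0-based col
  df <- data.frame(cell_id = ids,
                   centroid_row = rowsum(r0, f)[, 1] / npix,
                   centroid_col = rowsum(c0, f)[, 1] / npix)
  for (m in mk)
    df[[m]] <- rowsum(stack$markers[[m]]$pixels[idx], f)[, 1] / npix
  rownames(df) <- NULL
  cell_table(df, markers = mk, pixel_size_um = stack$pixel_size_um)
}

#' Call per-cell marker positivity
#'
#' A cell expresses a marker when its mean intensity is strictly greater
#' than the marker's threshold. The default threshold for every marker is
#' the global binarization threshold (60 counts), the same value that
#' defines anatomical masks; per-marker overrides come from
#' `config$positivity_threshold` (a named vector).
#'
#' @param cells a [cell_table()].
#' @param config an [analysis_config()].
#' @return A list of class `positivity_table`: logical `calls` matrix
#'   (cells x markers), per-marker `n_positive`, `n_any_positive` (cells
#'   expressing at least one marker), `cell_id`, and the thresholds used.
#' @export
call_positivity <- function(cells, config = analysis_config()) {
  if (!inherits(cells, "cell_table")) sm_stop("'cells' must be a cell_table")
  mk <- attr(cells, "markers")
  thr <- stats::setNames(rep(config$binary_threshold, length(mk)), mk)
  ov <- config$positivity_threshold
  if (!is.null(ov)) {
    if (is.null(names(ov)))
      sm_stop("'positivity_threshold' must be a named vector", "sm_config_error")
    unknown <- setdiff(names(ov), mk)
    if (length(unknown))
      sm_stop(paste0("positivity_threshold for unknown marker(s): ",
                     paste(unknown, collapse = ", ")), "sm_config_error")
    thr[names(ov)] <- ov
  }
  calls <- matrix(FALSE, nrow(cells), length(mk), dimnames = list(NULL, mk))
  for (m in mk) calls[, m] <- cells[[m]] > thr[[m]]
  structure(list(calls = calls,
                 n_positive = colSums(calls),
                 n_any_positive = sum(rowSums(calls) > 0),
                 cell_id = cells$cell_id,
                 thresholds = thr),
            class = "positivity_table")
}

#' @export
print.positivity_table <- function(x, ...) {
  cat(sprintf("<positivity_table> %d cells, %d any-positive\n",
              length(x$cell_id), x$n_any_positive))
  print(x$n_positive)
  invisible(x)
}

#' Percentage count of a marker
#'
#' Cells positive for the marker divided by cells positive for at least one
#' marker.
#'
#' @param pos a `positivity_table` from [call_positivity()].
#' @param marker marker name.
#' @return Fraction in `[0, 1]`.
#' @export
percentage_count <- function(pos, marker) {
  if (!inherits(pos, "positivity_table")) sm_stop("'pos' must be a positivity_table")
  if (!marker %in% colnames(pos$calls))
    sm_stop(paste0("unknown marker: ", marker), "sm_argument_error")
  if (pos$n_any_positive == 0)
    sm_stop("percentage count is undefined: no cell expresses any marker",
            "sm_undefined_error")
  unname(pos$n_positive[marker] / pos$n_any_positive)
}

#' Pearson correlation between two markers' single-cell intensities
#'
#' Standard Pearson r over per-cell mean intensities of all cells (no
#' positivity gating), with its Fisher transform `atanh(r)`.
#'
#' @param cells a [cell_table()].
#' @param m1,m2 marker names.
#' @param positive_only if `TRUE`, restrict to cells positive for either
#'   marker (threshold from `config`).
#' @param config an [analysis_config()] (used only when `positive_only`).
#' @return A list of class `correlation_result` with `marker_pair`, `r`,
#'   `n`, `z_fisher`.
#' @export
marker_correlation <- function(cells, m1, m2, positive_only = FALSE,
                               config = analysis_config()) {
  if (!inherits(cells, "cell_table")) sm_stop("'cells' must be a cell_table")
  mk <- attr(cells, "markers")
  if (!all(c(m1, m2) %in% mk))
    sm_stop("both markers must be columns of the cell table", "sm_argument_error")
  x <- cells[[m1]]; y <- cells[[m2]]
  if (positive_only) {
    pos <- call_positivity(cells, config)
    keep <- pos$calls[, m1] | pos$calls[, m2]
    x <- x[keep]; y <- y[keep]
  }
  n <- length(x)
  if (n < 3) sm_stop("need at least 3 cells for a correlation", "sm_argument_error")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    sm_stop("zero variance in a marker's intensities; correlation undefined",
            "sm_degenerate_error")
  r <- stats::cor(x, y)
  structure(list(marker_pair = c(m1, m2), r = r, n = n, z_fisher = atanh(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s vs %s: r = %.5f (n = %d, z = %.4f)\n",
              x$marker_pair[1], x$marker_pair[2], x$r, x$n, x$z_fisher))
  invisible(x)
}

#' Compare two Pearson correlations via the Fisher Z-transformation
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal tail p-value. Used to test whether a marker pair is more
#' strongly correlated in one condition than another.
#'
#' @param r1,r2 Pearson correlation coefficients, `|r| < 1`.
#' @param n1,n2 sample sizes (cells), both `> 3`.
#' @return A list with `z_statistic` and `two_sided_p`.
#' @export
compare_correlations_fisher <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3)
    sm_stop("Fisher comparison requires n > 3 in both samples", "sm_argument_error")
  if (abs(r1) >= 1 || abs(r2) >= 1)
    sm_stop("correlations must satisfy |r| < 1", "sm_argument_error")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z_statistic = z, two_sided_p = 2 * stats::pnorm(-abs(z)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the asymptotic two-sample p-value (the
#' sample sizes in its intended uses are large). Ties across samples are
#' tolerated; the ties warning from the underlying test is suppressed.
#'
#' @param sample_a,sample_b numeric vectors, both non-empty.
#' @return A list with `D_statistic` and `two_sided_p`.
#' @export
compare_distributions_ks <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    sm_stop("both samples must be non-empty", "sm_argument_error")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D_statistic = unname(kt$statistic), two_sided_p = unname(kt$p.value))
}

#' Box-plot style summary of a marker's single-cell intensities
#'
#' Quartiles by linear interpolation; outliers are values beyond
#' `q1 - 1.5 IQR` or `q3 + 1.5 IQR`; `min`/`max` exclude outliers.
#'
#' @param cells a [cell_table()].
#' @param marker marker name.
#' @return A list with `median`, `q1`, `q3`, `min`, `max`, `outliers`.
#' @export
intensity_summary <- function(cells, marker) {
  if (!inherits(cells, "cell_table")) sm_stop("'cells' must be a cell_table")
  if (!marker %in% attr(cells, "markers"))
    sm_stop(paste0("unknown marker: ", marker), "sm_argument_error")
  v <- cells[[marker]]
  if (length(v) == 0) sm_stop("cell table is empty", "sm_argument_error")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  out <- v[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
  kept <- if (length(out)) v[!v %in% out] else v
  list(median = q[2], q1 = q[1], q3 = q[3],
       min = min(kept), max = max(kept), outliers = sort(out))
}
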