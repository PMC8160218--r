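# Condition helper: user-facing errors carry a class so callers (and the CLI)
# can distinguish bad input from internal failure.
sm_stop <- function(msg, class = "sm_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "sm_error", "error")))
}

#' Single-marker intensity image
#'
#' A 2D grid of non-negative intensities (arbitrary count units, as exported
#' from IMC acquisitions) with a physical pixel size. All coordinates in the
#' package are 0-based `(row, col)` pixels; physical distances are always
#' `pixels * pixel_size_um`.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param marker_name marker (protein channel) name, e.g. `"CD68"`.
#' @param pixel_size_um physical edge length of one pixel in micrometers.
#' @return An object of class `marker_image` with fields `marker_name`,
#'   `pixels`, `pixel_size_um`.
#' @export
marker_image <- function(pixels, marker_name, pixel_size_um = 1) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || length(pixels) == 0L)
    sm_stop("'pixels' must be a non-empty numeric matrix", "sm_format_error")
  if (anyNA(pixels) || any(pixels < 0))
    sm_stop("marker intensities must be finite and >= 0", "sm_format_error")
  if (!is.character(marker_name) || length(marker_name) != 1L || !nzchar(marker_name))
    sm_stop("'marker_name' must be a single non-empty string", "sm_format_error")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0)
    sm_stop("'pixel_size_um' must be a single positive number", "sm_format_error")
  structure(list(marker_name = marker_name,
                 pixels = pixels,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<marker_image> %s  %d x %d px @ %g um/px  range [%g, %g]\n",
              x$marker_name, d[1], d[2], x$pixel_size_um,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Multi-marker image stack
#'
#' An ordered collection of [marker_image()]s sharing dimensions and pixel
#' size — one acquired ROI.
#'
#' @param images list of `marker_image` objects.
#' @param roi_id identifier for the region of interest.
#' @param condition_label condition tag, e.g. `"NT1"` or `"DT2"`.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(images, roi_id = "ROI", condition_label = "") {
  if (!is.list(images) || length(images) == 0L)
    sm_stop("'images' must be a non-empty list of marker_image objects", "sm_format_error")
  ok <- vapply(images, inherits, logical(1), what = "marker_image")
  if (!all(ok)) sm_stop("all elements of 'images' must be marker_image objects", "sm_format_error")
  dims <- vapply(images, function(im) dim(im$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    sm_stop("all marker images must share identical dimensions", "sm_dim_error")
  ps <- vapply(images, function(im) im$pixel_size_um, numeric(1))
  if (any(ps != ps[1]))
    sm_stop("all marker images must share the same pixel_size_um", "sm_format_error")
  nm <- vapply(images, function(im) im$marker_name, character(1))
  if (anyDuplicated(nm))
    sm_stop(paste0("duplicate marker name(s): ",
                   paste(unique(nm[duplicated(nm)]), collapse = ", ")),
            "sm_format_error")
  names(images) <- nm
  structure(list(roi_id = roi_id, condition_label = condition_label,
                 markers = images, pixel_size_um = ps[1]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$markers[[1]]$pixels)
  cat(sprintf("<image_stack> %s%s  %d markers  %d x %d px @ %g um/px\n",
              x$roi_id,
              if (nzchar(x$condition_label)) paste0(" [", x$condition_label, "]") else "",
              length(x$markers), d[1], d[2], x$pixel_size_um))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname image_stack
#' @param x an `image_stack`.
#' @export
marker_names <- function(x) names(x$markers)

stack_dim <- function(stack) dim(stack$markers[[1]]$pixels)

#' Cell segmentation label mask
#'
#' Integer-labeled grid: 0 is background, each positive integer is one cell.
#' Labels need not be consecutive and are never renumbered.
#'
#' @param labels integer-valued matrix, values >= 0.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, pixel_size_um = 1) {
  labels <- as.matrix(labels)
  if (!is.numeric(labels) || length(labels) == 0L)
    sm_stop("'labels' must be a non-empty numeric matrix", "sm_format_error")
  if (anyNA(labels) || any(labels != round(labels)) || any(labels < 0))
    sm_stop("label mask values must be non-negative integers", "sm_format_error")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %d x %d px  %d cells\n", d[1], d[2], n_cells(x)))
  invisible(x)
}

#' @rdname label_mask
#' @param x a `label_mask`.
#' @export
n_cells <- function(x) length(setdiff(unique(as.vector(x$labels)), 0L))

## ---- TIFF I/O -------------------------------------------------------------

read_tiff_grid <- function(path) {
  if (!file.exists(path))
    sm_stop(paste0("cannot read TIFF file: ", path), "sm_io_error")
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) sm_stop(
                    paste0("failed to read TIFF '", path, "': ", conditionMessage(e)),
                    "sm_io_error"))
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] != 1L)
      sm_stop(paste0("expected a single-channel TIFF: ", path), "sm_format_error")
    img <- img[, , 1]
  }
  img
}

write_tiff_grid <- function(grid, path) {
  if (anyNA(grid) || any(grid != round(grid)) || any(grid < 0) || any(grid > 65535))
    sm_stop("can only write integer grids in [0, 65535] as 16-bit TIFF", "sm_format_error")
  tiff::writeTIFF(grid / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

ome_channel_names <- function(description) {
  if (is.null(description) || !nzchar(description)) return(NULL)
  if (!grepl("<OME", description, fixed = TRUE)) return(NULL)
  if (!requireNamespace("xml2", quietly = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(description), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  ch <- xml2::xml_find_all(doc, "//*[local-name()='Channel']")
  nm <- xml2::xml_attr(ch, "Name")
  if (length(nm) == 0L || anyNA(nm)) return(NULL)
  nm
}

#' Read a marker image stack
#'
#' Reads either a directory of single-channel TIFFs (one per marker) or a
#' single multi-page (OME-)TIFF. Marker names come from OME channel metadata
#' when present, from `marker_names`, or from the file names with the TIFF
#' extension stripped. OME metadata and an explicit `marker_names` that
#' disagree are an error, not a warning: silent mislabeling is the worst
#' failure mode in multiplexed data.
#'
#' @param path directory of TIFF files or path to one multi-page TIFF.
#' @param pattern regular expression selecting files within a directory.
#' @param marker_names optional character vector of channel names.
#' @param pixel_size_um physical pixel size in micrometers.
#' @param roi_id,condition_label stack metadata.
#' @return An [image_stack()].
#' @export
read_marker_stack <- function(path, pattern = "\\.tiff?$", marker_names = NULL,
                              pixel_size_um = 1, roi_id = basename(path),
                              condition_label = "") {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L)
      sm_stop(paste0("no TIFF files matching pattern in ", path), "sm_io_error")
    nm <- if (!is.null(marker_names)) marker_names
          else sub("\\.tiff?$", "", basename(files), ignore.case = TRUE)
    if (length(nm) != length(files))
      sm_stop("length of 'marker_names' must match number of TIFF files", "sm_format_error")
    grids <- lapply(files, read_tiff_grid)
  } else if (file.exists(path)) {
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                      error = function(e) sm_stop(
                        paste0("failed to read TIFF '", path, "': ", conditionMessage(e)),
                        "sm_io_error"))
    grids <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    desc <- attr(pages[[1]], "description")
    ome <- ome_channel_names(desc)
    if (!is.null(ome) && length(ome) == length(grids)) {
      if (!is.null(marker_names) && !identical(marker_names, ome))
        sm_stop("'marker_names' conflicts with OME channel metadata", "sm_format_error")
      nm <- ome
    } else if (!is.null(marker_names)) {
      if (length(marker_names) != length(grids))
        sm_stop("length of 'marker_names' must match number of channels", "sm_format_error")
      nm <- marker_names
    } else {
      nm <- paste0("channel", seq_along(grids))
    }
  } else {
    sm_stop(paste0("no such file or directory: ", path), "sm_io_error")
  }
  imgs <- mapply(function(g, n) marker_image(g, n, pixel_size_um),
                 grids, nm, SIMPLIFY = FALSE)
  image_stack(imgs, roi_id = roi_id, condition_label = condition_label)
}

#' Write a marker image stack as a directory of 16-bit TIFFs
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if missing); one `<marker>.tiff` per
#'   channel.
#' @return The directory path, invisibly.
#' @export
write_marker_stack <- function(stack, dir) {
  if (!inherits(stack, "image_stack")) sm_stop("'stack' must be an image_stack")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(stack$markers))
    write_tiff_grid(stack$markers[[nm]]$pixels, file.path(dir, paste0(nm, ".tiff")))
  invisible(dir)
}

#' Read / write a segmentation label mask TIFF
#'
#' @param path TIFF file path.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, pixel_size_um = 1) {
  grid <- read_tiff_grid(path)
  if (any(grid != round(grid)))
    sm_stop(paste0("label mask contains non-integer pixel values: ", path),
            "sm_format_error")
  label_mask(grid, pixel_size_um = pixel_size_um)
}

#' @rdname read_label_mask
#' @param mask a [label_mask()].
#' @export
write_label_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask")) sm_stop("'mask' must be a label_mask")
  write_tiff_grid(mask$labels, path)
  invisible(path)
}

## ---- Cell table -----------------------------------------------------------

#' Single-cell expression table
#'
#' One row per segmented cell: unique `cell_id`, real-valued centroid in
#' 0-based `(row, col)` pixel coordinates, and one mean-intensity column per
#' marker (the CellProfiler MeasureObjectIntensity convention).
#'
#' @param df data.frame with columns `cell_id`, `centroid_row`,
#'   `centroid_col`, plus one numeric column per marker.
#' @param markers character vector naming the marker columns; defaults to all
#'   remaining columns.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A data.frame with class `cell_table` and attributes `markers` and
#'   `pixel_size_um`.
#' @export
cell_table <- function(df, markers = NULL, pixel_size_um = 1) {
  req <- c("cell_id", "centroid_row", "centroid_col")
  missing <- setdiff(req, names(df))
  if (length(missing))
    sm_stop(paste0("cell table is missing required column(s): ",
                   paste(missing, collapse = ", ")), "sm_schema_error")
  if (is.null(markers)) markers <- setdiff(names(df), req)
  if (anyDuplicated(df$cell_id))
    sm_stop("cell_id values must be unique", "sm_schema_error")
  for (m in markers)
    if (!is.numeric(df[[m]]))
      sm_stop(paste0("marker column '", m, "' must be numeric"), "sm_schema_error")
  df <- as.data.frame(df)[, c(req, markers), drop = FALSE]
  structure(df, class = c("cell_table", "data.frame"),
            markers = markers, pixel_size_um = pixel_size_um)
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d markers (%s)\n",
              nrow(x), length(attr(x, "markers")),
              paste(attr(x, "markers"), collapse = ", ")))
  NextMethod()
}

#' @rdname cell_table
#' @param path CSV file path (UTF-8, comma-separated, header row).
#' @export
read_cell_table <- function(path, pixel_size_um = 1) {
  if (!file.exists(path)) sm_stop(paste0("no such file: ", path), "sm_io_error")
  df <- utils::read.csv(path, check.names = FALSE)
  cell_table(df, pixel_size_um = pixel_size_um)
}

#' @rdname cell_table
#' @param tab a `cell_table`.
#' @export
write_cell_table <- function(tab, path) {
  if (!inherits(tab, "cell_table")) sm_stop("'tab' must be a cell_table")
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}

## ---- Analysis configuration ----------------------------------------------

#' Analysis configuration
#'
#' Central container for the fixed analysis parameters: the binary intensity
#' threshold (counts) shared by mask binarization and default cell
#' positivity, the k-means settings for anatomy clustering, neighbor counts
#' for the spatial distance machinery, the proximity cutoff, histogram
#' binning, percentile rescaling bounds, spring-layout parameters for the
#' cluster and reference networks, and the fixed landmark marker list.
#'
#' @param binary_threshold intensity threshold (counts) for binarization;
#'   strict `>` comparison.
#' @param kmeans_k number of anatomical clusters.
#' @param kmeans_n_init random restarts for k-means.
#' @param kmeans_max_iter,kmeans_tol k-means iteration cap and tolerance.
#' @param knn_k neighbors per cell for pairwise marker distances.
#' @param proximity_k neighbors for proximity maps (1 = nearest link).
#' @param proximity_cutoff_um distance cutoff for the below-cutoff fraction,
#'   in micrometers.
#' @param histogram_bins number of equal-width proximity histogram bins.
#' @param rescale_percentiles length-2 increasing percentile pair in
#'   `[0, 100]` for display rescaling.
#' @param spring_k_cluster,spring_iter_cluster spring-layout optimal distance
#'   and iterations for intra/inter cluster network maps.
#' @param spring_k_reference,spring_iter_reference spring-layout parameters
#'   for the fixed-landmark reference framework.
#' @param reference_edges_per_marker outgoing edges kept per marker in the
#'   reference graph.
#' @param landmark_markers markers held fixed in the reference framework.
#' @param positivity_threshold optional named per-marker thresholds
#'   overriding `binary_threshold` for cell positivity calls.
#' @param rng_seed integer seed for all stochastic steps.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(binary_threshold = 60,
                            kmeans_k = 6,
                            kmeans_n_init = 10,
                            kmeans_max_iter = 300,
                            kmeans_tol = 1e-4,
                            knn_k = 10,
                            proximity_k = 1,
                            proximity_cutoff_um = 30,
                            histogram_bins = 20,
                            rescale_percentiles = c(2, 98),
                            spring_k_cluster = 0.3,
                            spring_iter_cluster = 30,
                            spring_k_reference = 3.0,
                            spring_iter_reference = 5,
                            reference_edges_per_marker = 5,
                            landmark_markers = c("DNA1", "DNA2", "Histone3",
                                                 "CD3", "CD4", "CD8a", "CD20"),
                            positivity_threshold = NULL,
                            rng_seed = 1L) {
  counts <- c(kmeans_k = kmeans_k, kmeans_n_init = kmeans_n_init,
              kmeans_max_iter = kmeans_max_iter, knn_k = knn_k,
              proximity_k = proximity_k, histogram_bins = histogram_bins,
              spring_iter_cluster = spring_iter_cluster,
              spring_iter_reference = spring_iter_reference,
              reference_edges_per_marker = reference_edges_per_marker)
  if (any(counts < 1) || any(counts != round(counts)))
    sm_stop("all count parameters must be integers >= 1", "sm_config_error")
  if (length(rescale_percentiles) != 2 ||
      rescale_percentiles[1] >= rescale_percentiles[2] ||
      rescale_percentiles[1] < 0 || rescale_percentiles[2] > 100)
    sm_stop("'rescale_percentiles' must be strictly increasing within [0, 100]",
            "sm_config_error")
  if (proximity_cutoff_um <= 0)
    sm_stop("'proximity_cutoff_um' must be > 0", "sm_config_error")
  if (binary_threshold < 0)
    sm_stop("'binary_threshold' must be >= 0", "sm_config_error")
  structure(list(binary_threshold = binary_threshold,
                 kmeans_k = as.integer(kmeans_k),
                 kmeans_n_init = as.integer(kmeans_n_init),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 kmeans_tol = kmeans_tol,
                 knn_k = as.integer(knn_k),
                 proximity_k = as.integer(proximity_k),
                 proximity_cutoff_um = proximity_cutoff_um,
                 histogram_bins = as.integer(histogram_bins),
                 rescale_percentiles = rescale_percentiles,
                 spring_k_cluster = spring_k_cluster,
                 spring_iter_cluster = as.integer(spring_iter_cluster),
                 spring_k_reference = spring_k_reference,
                 spring_iter_reference = as.integer(spring_iter_reference),
                 reference_edges_per_marker = as.integer(reference_edges_per_marker),
                 landmark_markers = landmark_markers,
                 positivity_threshold = positivity_threshold,
                 rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) sm_stop(paste0("no such file: ", path), "sm_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  do.call(analysis_config, vals[intersect(names(vals), known)])
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Convert a pixel distance to micrometers
#'
#' @param d_px distance in pixels.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return Distance in micrometers.
#' @export
px_to_um <- function(d_px, pixel_size_um) d_px * pixel_size_um
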