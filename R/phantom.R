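## Synthetic tissue phantoms: image stacks, label masks and cell tables with
## planted anatomical regions, marker enrichment and coexpression, so every
## downstream stage can be checked against ground truth.

#' Geometric region primitives for tissue phantoms
#'
#' Regions are painted in list order; where primitives overlap, the later
#' region wins, so every pixel (and every cell) belongs to exactly one region.
#'
#' @param id positive integer region id.
#' @param center `(row, col)` center in 0-based pixel coordinates.
#' @param radius,r_inner,r_outer radii in pixels.
#' @param axis `"row"` or `"col"`.
#' @param from,to band bounds (inclusive) along `axis`, 0-based pixels.
#' @param at,side half-plane boundary coordinate and side (`"low"` keeps
#'   coordinates `< at`, `"high"` keeps `>= at`).
#' @return A list of class `phantom_region`.
#' @name phantom_region
NULL

#' @rdname phantom_region
#' @export
region_disc <- function(id, center, radius) {
  structure(list(kind = "disc", id = as.integer(id), center = center,
                 radius = radius), class = "phantom_region")
}

#' @rdname phantom_region
#' @export
region_annulus <- function(id, center, r_inner, r_outer) {
  if (r_inner >= r_outer) sm_stop("annulus requires r_inner < r_outer")
  structure(list(kind = "annulus", id = as.integer(id), center = center,
                 r_inner = r_inner, r_outer = r_outer), class = "phantom_region")
}

#' @rdname phantom_region
#' @export
region_band <- function(id, axis = c("row", "col"), from, to) {
  axis <- match.arg(axis)
  structure(list(kind = "band", id = as.integer(id), axis = axis,
                 from = from, to = to), class = "phantom_region")
}

#' @rdname phantom_region
#' @export
region_halfplane <- function(id, axis = c("row", "col"), at, side = c("low", "high")) {
  axis <- match.arg(axis); side <- match.arg(side)
  structure(list(kind = "halfplane", id = as.integer(id), axis = axis,
                 at = at, side = side), class = "phantom_region")
}

region_footprint <- function(region, dims) {
  r0 <- matrix(rep(seq_len(dims[1]) - 1, dims[2]), dims[1], dims[2])
  c0 <- matrix(rep(seq_len(dims[2]) - 1, each = dims[1]), dims[1], dims[2])
  switch(region$kind,
    disc = (r0 - region$center[1])^2 + (c0 - region$center[2])^2 <= region$radius^2,
    annulus = {
      d2 <- (r0 - region$center[1])^2 + (c0 - region$center[2])^2
      d2 >= region$r_inner^2 & d2 <= region$r_outer^2
    },
    band = {
      v <- if (region$axis == "row") r0 else c0
      v >= region$from & v <= region$to
    },
    halfplane = {
      v <- if (region$axis == "row") r0 else c0
      if (region$side == "low") v < region$at else v >= region$at
    })
}

#' Tissue phantom specification
#'
#' Defines a synthetic ROI: geometric anatomical regions, per-marker region
#' enrichment and background baseline, per-region cell density, cell size,
#' optional marker-pair coexpression probabilities, and the intensity noise
#' level. Intensities are integer counts on the IMC scale, so the default
#' baseline (5 counts) sits well below and the default enrichment (150
#' counts) well above the standard binarization threshold of 60.
#'
#' @param image_size `(rows, cols)` in pixels. 500 x 500 by default: a
#'   desk-scale stand-in for a full acquisition field, with the full ROI
#'   scale available by configuration.
#' @param regions list of [phantom_region] primitives.
#' @param marker_profiles named list, one entry per marker:
#'   `list(baseline = <counts>, enrichment = c(<region_id> = <counts>, ...))`.
#' @param cell_density cells per 100 x 100 px, either a single number or a
#'   vector named by region id.
#' @param cell_radius_px cell disc radius in pixels.
#' @param coexpression optional list of `list(m1 =, m2 =, prob =)` entries:
#'   probability that a cell positive for one marker of the pair is also
#'   positive for the other.
#' @param intensity_noise_sd standard deviation (counts) of per-cell Gaussian
#'   noise, clipped at zero.
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = c(500, 500),
                         regions,
                         marker_profiles,
                         cell_density = 20,
                         cell_radius_px = 4,
                         coexpression = NULL,
                         intensity_noise_sd = 0,
                         seed = 1L,
                         pixel_size_um = 1) {
  if (length(image_size) != 2 || any(image_size < 1))
    sm_stop("'image_size' must be two positive integers")
  if (!length(regions) || !all(vapply(regions, inherits, logical(1), "phantom_region")))
    sm_stop("'regions' must be a non-empty list of phantom_region objects")
  ids <- vapply(regions, function(r) r$id, integer(1))
  if (anyDuplicated(ids)) sm_stop("region ids must be unique")
  if (is.null(names(marker_profiles)) || !all(nzchar(names(marker_profiles))))
    sm_stop("'marker_profiles' must be a named list (one entry per marker)")
  if (any(cell_density < 0)) sm_stop("cell densities must be >= 0")
  if (!is.null(coexpression))
    for (cx in coexpression)
      if (cx$prob < 0 || cx$prob > 1)
        sm_stop("coexpression probabilities must be in [0, 1]")
  if (intensity_noise_sd < 0) sm_stop("'intensity_noise_sd' must be >= 0")
  structure(list(image_size = as.integer(image_size), regions = regions,
                 marker_profiles = marker_profiles,
                 cell_density = cell_density,
                 cell_radius_px = cell_radius_px,
                 coexpression = coexpression,
                 intensity_noise_sd = intensity_noise_sd,
                 seed = as.integer(seed),
                 pixel_size_um = pixel_size_um),
            class = "phantom_spec")
}

disc_offsets <- function(radius) {
  r <- ceiling(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius^2
  cbind(dr[keep], dc[keep])
}

#' Generate a tissue phantom
#'
#' Renders the phantom described by a [phantom_spec()]: builds the region
#' map, places non-overlapping cell discs by rejection sampling inside each
#' region, draws per-cell marker positivity from the enrichment profile and
#' coexpression rules, and paints marker images as
#' `baseline + enrichment x positivity + noise` (clipped at zero, rounded to
#' integer counts). Region footprints are painted with the enrichment value
#' outside cell discs, so the binarized marker mask reproduces the anatomical
#' footprint while per-cell intensities still encode single-cell positivity.
#' The emitted cell table is recomputed from the rendered images and mask by
#' [quantify_cells()], not copied from ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `tissue_phantom` with elements `stack`
#'   ([image_stack()]), `mask` ([label_mask()]), `cells` ([cell_table()]),
#'   and `truth` (region map, true marker grouping, cell positions and
#'   per-cell true positivity).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) sm_stop("'spec' must be a phantom_spec")
  set.seed(spec$seed)
  dims <- spec$image_size
  markers <- names(spec$marker_profiles)

  region_map <- matrix(0L, dims[1], dims[2])
  for (rg in spec$regions) region_map[region_footprint(rg, dims)] <- rg$id
  region_ids <- vapply(spec$regions, function(r) r$id, integer(1))

  ## --- place cells (rejection sampling of non-overlapping discs) ----------
  rad <- spec$cell_radius_px
  dens <- spec$cell_density
  centers <- matrix(numeric(0), 0, 2)
  cell_region <- integer(0)
  for (rg_id in region_ids) {
    d <- if (length(dens) > 1 && !is.null(names(dens))) {
      if (is.na(dens[as.character(rg_id)])) 0 else dens[[as.character(rg_id)]]
    } else dens[[1]]
    area_px <- sum(region_map == rg_id)
    n_target <- round(d * area_px / 1e4)
    placed <- 0
    while (placed < n_target) {
      ok <- FALSE
      for (attempt in seq_len(1000L)) {
        r0 <- stats::runif(1, rad, dims[1] - 1 - rad)
        c0 <- stats::runif(1, rad, dims[2] - 1 - rad)
        if (region_map[floor(r0) + 1, floor(c0) + 1] != rg_id) next
        if (nrow(centers) &&
            any((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2 < (2 * rad)^2)) next
        ok <- TRUE
        break
      }
      if (!ok)
        sm_stop(paste0("could not place cell ", placed + 1, " in region ", rg_id,
                       " after 1000 attempts; lower cell_density"),
                "sm_generation_error")
      centers <- rbind(centers, c(r0, c0))
      cell_region <- c(cell_region, rg_id)
      placed <- placed + 1
    }
  }
  n_cell <- nrow(centers)

  ## --- true positivity -----------------------------------------------------
  enrich <- function(m, rg_id) {
    e <- spec$marker_profiles[[m]]$enrichment
    if (is.null(e) || !as.character(rg_id) %in% names(e)) 0 else e[[as.character(rg_id)]]
  }
  positivity <- matrix(FALSE, n_cell, length(markers),
                       dimnames = list(NULL, markers))
  for (j in seq_along(markers))
    if (n_cell)
      positivity[, j] <- vapply(cell_region, function(rg) enrich(markers[j], rg) > 0,
                                logical(1))
  if (!is.null(spec$coexpression) && n_cell)
    for (cx in spec$coexpression) {
      p1 <- positivity[, cx$m1]; p2 <- positivity[, cx$m2]
      gain2 <- p1 & !p2 & stats::runif(n_cell) < cx$prob
      gain1 <- p2 & !p1 & stats::runif(n_cell) < cx$prob
      positivity[gain2, cx$m2] <- TRUE
      positivity[gain1, cx$m1] <- TRUE
    }

  ## --- render mask ---------------------------------------------------------
  labels <- matrix(0L, dims[1], dims[2])
  offs <- disc_offsets(rad)
  cell_pix <- vector("list", n_cell)
  for (i in seq_len(n_cell)) {
    rr <- round(centers[i, 1]) + offs[, 1] + 1
    cc <- round(centers[i, 2]) + offs[, 2] + 1
    keep <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
    idx <- cbind(rr[keep], cc[keep])
    labels[idx] <- i
    cell_pix[[i]] <- idx
  }
  mask <- label_mask(labels, pixel_size_um = spec$pixel_size_um)

  ## --- render marker images ------------------------------------------------
  imgs <- vector("list", length(markers))
  for (j in seq_along(markers)) {
    m <- markers[j]
    base <- spec$marker_profiles[[m]]$baseline
    if (is.null(base)) base <- 0
    img <- matrix(base, dims[1], dims[2])
    for (rg_id in region_ids) {
      e <- enrich(m, rg_id)
      if (e > 0) img[region_map == rg_id] <- base + e
    }
    max_e <- if (is.null(spec$marker_profiles[[m]]$enrichment)) 0
             else max(spec$marker_profiles[[m]]$enrichment)
    for (i in seq_len(n_cell)) {
      level <- if (positivity[i, j]) {
        e <- enrich(m, cell_region[i])
        if (e > 0) e else max_e    # coexpression-forced positives express at the marker's peak level
      } else 0
      val <- base + level +
        if (spec$intensity_noise_sd > 0) stats::rnorm(1, 0, spec$intensity_noise_sd) else 0
      img[cell_pix[[i]]] <- max(0, val)
    }
    imgs[[j]] <- marker_image(round(pmin(img, 65535)), m,
                              pixel_size_um = spec$pixel_size_um)
  }
  stack <- image_stack(imgs, roi_id = "phantom", condition_label = "synthetic")

  cells <- quantify_cells(stack, mask)

  dominant <- vapply(markers, function(m) {
    e <- vapply(region_ids, function(rg) enrich(m, rg), numeric(1))
    if (all(e == 0)) 0L else region_ids[which.max(e)]
  }, integer(1))
  truth <- list(region_map = region_map,
                true_marker_grouping = split(markers, dominant),
                cell_positions = centers,
                cell_region = cell_region,
                true_positivity = positivity)

  structure(list(stack = stack, mask = mask, cells = cells, truth = truth,
                 spec = spec),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- stack_dim(x$stack)
  cat(sprintf("<tissue_phantom> %d x %d px, %d markers, %d cells, %d regions\n",
              d[1], d[2], length(x$stack$markers), nrow(x$cells),
              length(x$spec$regions)))
  invisible(x)
}

#' Generate a planted-offset point pattern
#'
#' Builds two centroid sets A and B: each B point sits at a fixed-magnitude
#' offset in a random direction from an A point, plus per-coordinate
#' Gaussian jitter. The A points are laid on a jittered grid whose spacing
#' guarantees that every A point's nearest B point is its own planted
#' partner, so the expected A-to-B nearest-neighbor distance equals the
#' planted offset (up to jitter) by construction — the property the pattern
#' exists to provide. Surplus B points (when `n_b > n_a`) are uniform over
#' the frame.
#'
#' @param n_a,n_b point counts (both >= 1).
#' @param planted_offset_um offset magnitude in micrometers (>= 0).
#' @param jitter_sd per-coordinate Gaussian jitter SD in micrometers.
#' @param seed integer RNG seed.
#' @param pixel_size_um physical pixel size in micrometers.
#' @return A list with `point_set` elements `a` and `b`, plus `frame`
#'   (the `(rows, cols)` extent used).
#' @export
generate_point_pattern <- function(n_a, n_b, planted_offset_um, jitter_sd = 0,
                                   seed = 1L, pixel_size_um = 1) {
  if (n_a < 1 || n_b < 1) sm_stop("'n_a' and 'n_b' must be >= 1")
  if (planted_offset_um < 0)
    sm_stop("'planted_offset_um' must be >= 0", "sm_argument_error")
  set.seed(seed)
  off_px <- planted_offset_um / pixel_size_um
  jit_px <- jitter_sd / pixel_size_um
  # grid spacing: 4x the offset scale keeps foreign partners at least ~2x
  # the offset away even after jitter
  spacing <- max(4 * (off_px + 5 * jit_px + 1), 10)
  side <- ceiling(sqrt(n_a))
  frame <- c(side, side) * spacing
  cells <- sample.int(side * side, n_a)          # random grid cells
  gr <- (cells - 1) %/% side
  gc <- (cells - 1) %% side
  a <- cbind(gr * spacing + spacing / 2, gc * spacing + spacing / 2) +
    matrix(stats::runif(2 * n_a, -spacing / 8, spacing / 8), n_a, 2)
  m <- min(n_a, n_b)
  theta <- stats::runif(m, 0, 2 * pi)
  b <- a[seq_len(m), , drop = FALSE] +
    cbind(off_px * cos(theta), off_px * sin(theta))
  if (jit_px > 0) b <- b + matrix(stats::rnorm(2 * m, 0, jit_px), m, 2)
  if (n_b > n_a)
    b <- rbind(b, cbind(stats::runif(n_b - n_a, 0, frame[1]),
                        stats::runif(n_b - n_a, 0, frame[2])))
  list(a = point_set("A", a, pixel_size_um),
       b = point_set("B", b, pixel_size_um),
       frame = frame)
}
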