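## Pipeline runner: wires the modules into the bottom-up (single-cell) and
## top-down (anatomy) analyses with one config, per-stage derived seeds and
## a reproducibility manifest.

PIPELINE_STAGES <- c("simulate", "quantify", "stats", "anatomy",
                     "distances", "proximity", "topography", "network")

# Stable per-stage seed derived from the global seed by hashing the stage
# name, kept below 2^31.
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}

default_pipeline_spec <- function(seed) {
  list(
    image_size = c(500, 500),
    regions = list(list(kind = "disc", id = 1, center = c(150, 150), radius = 110),
                   list(kind = "disc", id = 2, center = c(350, 350), radius = 110)),
    markers = list(
      DNA1 = list(baseline = 5, enrichment = c("1" = 150, "2" = 150)),
      CD3 = list(baseline = 5, enrichment = c("1" = 150)),
      CD4 = list(baseline = 5, enrichment = c("1" = 140)),
      CD20 = list(baseline = 5, enrichment = c("2" = 150)),
      CD68 = list(baseline = 5, enrichment = c("2" = 140)),
      GranzymeB = list(baseline = 5, enrichment = c("2" = 130))),
    cell_density = 12,
    cell_radius_px = 4,
    intensity_noise_sd = 0,
    seed = seed)
}

parse_region <- function(r) {
  switch(r$kind,
    disc = region_disc(r$id, unlist(r$center), r$radius),
    annulus = region_annulus(r$id, unlist(r$center), r$r_inner, r$r_outer),
    band = region_band(r$id, r$axis, r$from, r$to),
    halfplane = region_halfplane(r$id, r$axis, r$at, r$side),
    sm_stop(paste0("unknown region kind: ", r$kind), "sm_config_error"))
}

phantom_spec_from_config <- function(ph, seed) {
  profiles <- lapply(ph$markers, function(m)
    list(baseline = m$baseline,
         enrichment = if (!is.null(m$enrichment)) unlist(m$enrichment)))
  phantom_spec(image_size = unlist(ph$image_size),
               regions = lapply(ph$regions, parse_region),
               marker_profiles = profiles,
               cell_density = ph$cell_density,
               cell_radius_px = ph$cell_radius_px,
               coexpression = ph$coexpression,
               intensity_noise_sd = if (is.null(ph$intensity_noise_sd)) 0
                                    else ph$intensity_noise_sd,
               seed = seed)
}

require_artifact <- function(path, stage, needed_by) {
  if (!file.exists(path))
    sm_stop(paste0("stage '", needed_by, "' requires output of stage '", stage,
                   "' (missing: ", path, "); run it first or include it in 'stages'"),
            "sm_dependency_error")
  path
}

write_num_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on one dataset,
#' writing every artifact under `out_dir` and a JSON run manifest (config
#' snapshot, input digests, seed, per-stage outputs and wall time). Given
#' the same config and seed the numeric outputs are byte-identical across
#' runs. Stages: `simulate` (tissue phantom: TIFF stack, mask, cells.csv,
#' ground_truth.json), `quantify` (cells.csv from stack + mask), `stats`
#' (positivity counts, percentage counts, pairwise correlations),
#' `anatomy` (marker-cluster assignment, area ratios, cluster mean images),
#' `distances` (pairwise k-NN matrix, intra/inter cluster edge lists),
#' `proximity` (nearest links and histograms per pair), `topography`
#' (per-marker peaks), `network` (intra/inter/reference GraphML + layout
#' positions).
#'
#' @param config path to a YAML config file or an equivalent list. Keys:
#'   `seed`, `analysis` (arguments of [analysis_config()]), `phantom`
#'   (phantom description for `simulate`), `pairs` (marker pairs for
#'   `proximity`), `topography` (`markers`, `sigma_px`, `stride`),
#'   `stack_dir`/`mask_path` (inputs when `simulate` is not run).
#' @param stages character vector, a subset of the stage names above, run
#'   in canonical order.
#' @param out_dir output directory.
#' @return The run manifest (list of class `run_manifest`), invisibly
#'   written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), stages = PIPELINE_STAGES,
                         out_dir = "spatialmux_out") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    sm_stop(paste0("unknown stage(s): ", paste(bad, collapse = ", ")),
            "sm_config_error")
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cfg <- do.call(analysis_config,
                 c(config$analysis, list(rng_seed = seed))[
                   !duplicated(names(c(config$analysis, list(rng_seed = seed))),
                               fromLast = TRUE)])
  manifest <- list(tool = "spatialmux",
                   version = as.character(utils::packageVersion("spatialmux")),
                   seed = seed, config = config, stages = list())
  paths <- list(stack_dir = file.path(out_dir, "stack"),
                mask = file.path(out_dir, "mask.tiff"),
                cells = file.path(out_dir, "cells.csv"),
                truth = file.path(out_dir, "ground_truth.json"),
                assignment = file.path(out_dir, "assignment.csv"),
                areas = file.path(out_dir, "area_ratios.csv"),
                dmatrix = file.path(out_dir, "distance_matrix.csv"))
  if (!is.null(config$stack_dir)) paths$stack_dir <- config$stack_dir
  if (!is.null(config$mask_path)) paths$mask <- config$mask_path

  log_stage <- function(name, outputs, elapsed) {
    message(sprintf("[spatialmux] %-10s done in %.2fs: %s", name, elapsed,
                    paste(basename(unlist(outputs)), collapse = ", ")))
    manifest$stages[[name]] <<- list(outputs = unlist(outputs),
                                     wall_time_s = elapsed)
  }

  for (stage in stages) {
    t0 <- proc.time()[["elapsed"]]
    outputs <- switch(stage,
      simulate = {
        ph <- if (is.null(config$phantom)) default_pipeline_spec(stage_seed(seed, "simulate"))
              else config$phantom
        spec <- phantom_spec_from_config(ph, stage_seed(seed, "simulate"))
        phantom <- generate_phantom(spec)
        write_marker_stack(phantom$stack, paths$stack_dir)
        write_label_mask(phantom$mask, paths$mask)
        write_cell_table(phantom$cells, paths$cells)
        jsonlite::write_json(
          list(true_marker_grouping = phantom$truth$true_marker_grouping,
               n_cells = nrow(phantom$cells),
               cell_region = phantom$truth$cell_region),
          paths$truth, auto_unbox = TRUE, digits = NA)
        list(paths$stack_dir, paths$mask, paths$cells, paths$truth)
      },
      quantify = {
        require_artifact(paths$stack_dir, "simulate", "quantify")
        require_artifact(paths$mask, "simulate", "quantify")
        stack <- read_marker_stack(paths$stack_dir)
        mask <- read_label_mask(paths$mask)
        cells <- quantify_cells(stack, mask)
        write_cell_table(cells, paths$cells)
        message(sprintf("[spatialmux] quantified %d cells x %d markers",
                        nrow(cells), length(attr(cells, "markers"))))
        list(paths$cells)
      },
      stats = {
        require_artifact(paths$cells, "quantify", "stats")
        cells <- read_cell_table(paths$cells)
        pos <- call_positivity(cells, cfg)
        mk <- attr(cells, "markers")
        counts <- data.frame(marker = mk,
                             n_positive = unname(pos$n_positive[mk]),
                             percentage_count = vapply(mk, function(m)
                               if (pos$n_any_positive > 0)
                                 percentage_count(pos, m) else NA_real_,
                               numeric(1)))
        f1 <- write_num_csv(counts, file.path(out_dir, "positivity_counts.csv"))
        pairs <- utils::combn(mk, 2)
        cors <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
          res <- tryCatch(marker_correlation(cells, pairs[1, p], pairs[2, p]),
                          error = function(e) NULL)
          if (is.null(res)) return(NULL)
          data.frame(m1 = pairs[1, p], m2 = pairs[2, p], r = res$r, n = res$n,
                     z_fisher = res$z_fisher)
        }))
        f2 <- write_num_csv(cors, file.path(out_dir, "correlations.csv"))
        list(f1, f2)
      },
      anatomy = {
        require_artifact(paths$stack_dir, "simulate", "anatomy")
        stack <- read_marker_stack(paths$stack_dir)
        bm <- binarize_stack(stack, cfg$binary_threshold)
        assignment <- cluster_markers_kmeans(bm, k = cfg$kmeans_k, config = cfg,
                                             seed = stage_seed(seed, "anatomy"))
        f1 <- write_num_csv(data.frame(marker = names(assignment),
                                       cluster = as.integer(assignment)),
                            paths$assignment)
        ar <- area_ratios(stack, cfg$binary_threshold)
        f2 <- write_num_csv(data.frame(marker = names(ar),
                                       area_ratio = unname(ar)), paths$areas)
        mdir <- file.path(out_dir, "cluster_means")
        dir.create(mdir, showWarnings = FALSE)
        for (cl in seq_len(attr(assignment, "K"))) {
          mi <- cluster_mean_image(stack, assignment, cl)
          write_tiff_grid(round(mi$pixels),
                          file.path(mdir, paste0("cluster_", cl, ".tiff")))
        }
        message(sprintf("[spatialmux] anatomy: %d markers -> %d clusters",
                        length(assignment), attr(assignment, "K")))
        list(f1, f2, mdir)
      },
      distances = {
        require_artifact(paths$cells, "quantify", "distances")
        cells <- read_cell_table(paths$cells)
        pts <- points_by_marker(cells, cfg)
        M <- marker_pair_distance_matrix(pts, k = cfg$knn_k)
        f1 <- write_num_csv(data.frame(marker = rownames(M), M,
                                       check.names = FALSE), paths$dmatrix)
        outs <- list(f1)
        if (file.exists(paths$assignment)) {
          adf <- utils::read.csv(paths$assignment)
          assignment <- structure(stats::setNames(adf$cluster, adf$marker),
                                  K = max(adf$cluster), class = "cluster_assignment")
          keep <- intersect(rownames(M), names(assignment))
          intra <- intra_cluster_distances(M[keep, keep, drop = FALSE], assignment)
          outs <- c(outs, write_num_csv(intra, file.path(out_dir, "intra_cluster.csv")))
          cls <- sort(unique(adf$cluster))
          if (length(cls) >= 2) {
            cp <- utils::combn(cls, 2)
            inter <- data.frame(c1 = cp[1, ], c2 = cp[2, ],
                                distance_um = vapply(seq_len(ncol(cp)), function(p)
                                  inter_cluster_distance(M[keep, keep, drop = FALSE],
                                                         assignment, cp[1, p], cp[2, p]),
                                  numeric(1)))
            outs <- c(outs, write_num_csv(inter, file.path(out_dir, "inter_cluster.csv")))
          }
        }
        outs
      },
      proximity = {
        require_artifact(paths$cells, "quantify", "proximity")
        cells <- read_cell_table(paths$cells)
        pts <- points_by_marker(cells, cfg)
        mk <- names(pts)
        pairs <- config$pairs
        if (is.null(pairs)) {
          nonempty <- mk[vapply(pts, function(p) nrow(p$centroids) > 0, logical(1))]
          pairs <- if (length(nonempty) >= 2) list(nonempty[1:2]) else list()
        }
        outs <- list()
        for (pr in pairs) {
          pr <- unlist(pr)
          links <- proximity_histogram(nearest_links(pts[[pr[1]]], pts[[pr[2]]]),
                                       bins = cfg$histogram_bins)
          tag <- paste0(pr[1], "_", pr[2])
          outs <- c(outs,
            write_num_csv(links$links, file.path(out_dir, paste0("links_", tag, ".csv"))),
            write_num_csv(data.frame(bin_low = links$bin_edges[-length(links$bin_edges)],
                                     bin_high = links$bin_edges[-1],
                                     proportion = links$proportions),
                          file.path(out_dir, paste0("histogram_", tag, ".csv"))))
        }
        hm <- average_proximity_heatmap(pts, k = cfg$proximity_k)
        outs <- c(outs, write_num_csv(data.frame(marker = rownames(hm), hm,
                                                 check.names = FALSE),
                                      file.path(out_dir, "proximity_heatmap.csv")))
        outs
      },
      topography = {
        require_artifact(paths$stack_dir, "simulate", "topography")
        stack <- read_marker_stack(paths$stack_dir)
        tp <- config$topography
        mks <- if (!is.null(tp$markers)) unlist(tp$markers) else marker_names(stack)
        sigma <- if (is.null(tp$sigma_px)) 5 else tp$sigma_px
        stride <- if (is.null(tp$stride)) 4 else tp$stride
        pk <- do.call(rbind, lapply(mks, function(m) {
          grid <- make_topography(stack$markers[[m]], sigma_px = sigma,
                                  stride = stride)
          ps <- find_peaks(grid, min_height = cfg$binary_threshold,
                           min_separation_px = 10 * stride)
          if (nrow(ps$peaks) == 0) return(NULL)
          cbind(marker = m, ps$peaks)
        }))
        if (is.null(pk))
          pk <- data.frame(marker = character(0), row = numeric(0),
                           col = numeric(0), height = numeric(0))
        list(write_num_csv(pk, file.path(out_dir, "peaks.csv")))
      },
      network = {
        require_artifact(paths$dmatrix, "distances", "network")
        require_artifact(paths$assignment, "anatomy", "network")
        require_artifact(paths$areas, "anatomy", "network")
        mdf <- utils::read.csv(paths$dmatrix, check.names = FALSE)
        M <- as.matrix(mdf[, -1, drop = FALSE])
        rownames(M) <- mdf$marker
        adf <- utils::read.csv(paths$assignment)
        assignment <- structure(stats::setNames(adf$cluster, adf$marker),
                                K = max(adf$cluster), class = "cluster_assignment")
        ardf <- utils::read.csv(paths$areas)
        ar <- stats::setNames(ardf$area_ratio, ardf$marker)
        keep <- intersect(rownames(M), names(assignment))
        Mk <- M[keep, keep, drop = FALSE]
        outs <- list()
        for (mode in c("intra", "inter")) {
          g <- build_cluster_graph(Mk, assignment, ar, mode = mode)
          pos <- layout_spring(g, k = cfg$spring_k_cluster,
                               iterations = cfg$spring_iter_cluster,
                               seed = stage_seed(seed, paste0("network_", mode)))
          f <- file.path(out_dir, paste0("network_", mode, ".graphml"))
          write_spatial_graph(g, f, positions = pos)
          fp <- write_num_csv(data.frame(node = rownames(pos), x = pos[, 1],
                                         y = pos[, 2]),
                              file.path(out_dir, paste0("positions_", mode, ".csv")))
          outs <- c(outs, f, fp)
        }
        ref_cfg <- cfg
        ref_cfg$landmark_markers <- intersect(cfg$landmark_markers, keep)
        if (length(ref_cfg$landmark_markers) >= 1) {
          g <- build_reference_graph(Mk, ar, ref_cfg)
          pos <- layout_reference(g, ref_cfg, seed = stage_seed(seed, "network_ref"))
          f <- file.path(out_dir, "network_reference.graphml")
          write_spatial_graph(g, f, positions = pos)
          fp <- write_num_csv(data.frame(node = rownames(pos), x = pos[, 1],
                                         y = pos[, 2]),
                              file.path(out_dir, "positions_reference.csv"))
          outs <- c(outs, f, fp)
        }
        outs
      })
    log_stage(stage, outputs, proc.time()[["elapsed"]] - t0)
  }

  files <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  files <- files[file.exists(files) & !dir.exists(files)]
  manifest$input_digests <- as.list(tools::md5sum(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> spatialmux %s, seed %d, %d stage(s)\n",
              x$version, x$seed, length(x$stages)))
  for (s in names(x$stages))
    cat(sprintf("  %-10s %.2fs  %d output(s)\n", s, x$stages[[s]]$wall_time_s,
                length(x$stages[[s]]$outputs)))
  invisible(x)
}
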