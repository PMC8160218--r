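mk_assignment <- function(v, K = max(v)) {
  structure(as.integer(v), names = names(v), K = as.integer(K),
            class = "cluster_assignment")
}

test_that("cluster graphs carry sizes, weights and the degenerate normalization", {
  M <- matrix(c(0, 10, 10, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  asg <- mk_assignment(c(a = 1, b = 1))
  ar <- c(a = 0.2, b = 0.4)
  g <- build_cluster_graph(M, asg, ar, "intra")
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$normalized_weight, 0)   # single edge normalizes to 0
  expect_equal(igraph::V(g)$size, c(0.2, 0.4))

  solo <- build_cluster_graph(M, mk_assignment(c(a = 1, b = 2)), ar, "intra")
  expect_equal(igraph::ecount(solo), 0)
  expect_equal(igraph::vcount(solo), 2)
})

test_that("normalized weights span [0,1] with two or more distinct weights", {
  nm <- c("a", "b", "c", "d")
  M <- matrix(runif(16, 5, 50), 4, 4, dimnames = list(nm, nm)); diag(M) <- 0
  g <- build_cluster_graph(M, mk_assignment(setNames(rep(1, 4), nm)),
                           setNames(runif(4), nm), "intra")
  nw <- igraph::E(g)$normalized_weight
  expect_equal(min(nw), 0); expect_equal(max(nw), 1)
  expect_true(all(nw >= 0 & nw <= 1))
})

test_that("inter-mode edges order consistently with planted region separation", {
  spec <- phantom_spec(
    image_size = c(300, 300),
    regions = list(region_disc(1, c(70, 70), 40),
                   region_disc(2, c(70, 230), 40),
                   region_disc(3, c(230, 150), 40)),
    marker_profiles = list(A = list(baseline = 5, enrichment = c("1" = 150)),
                           B = list(baseline = 5, enrichment = c("2" = 150)),
                           C = list(baseline = 5, enrichment = c("3" = 150))),
    cell_density = 20, cell_radius_px = 3, seed = 5)
  ph <- generate_phantom(spec)
  pts <- points_by_marker(ph$cells)
  M <- marker_pair_distance_matrix(pts, k = 1)
  asg <- mk_assignment(c(A = 1, B = 2, C = 3))
  g <- build_cluster_graph(M, asg, setNames(rep(0.1, 3), c("A", "B", "C")), "inter")
  ew <- igraph::E(g)$weight_um[igraph::E(g)$kind == "distance"]
  expect_length(ew, 3)
  # region centroid separations: 1-2 = 160, 1-3 = sqrt(160^2+80^2), 2-3 same
  d12 <- inter_cluster_distance(M, asg, 1, 2)
  d13 <- inter_cluster_distance(M, asg, 1, 3)
  expect_lt(d12, d13)
  # membership edges exist for every marker
  expect_equal(sum(igraph::E(g)$kind == "membership"), 3)
})

test_that("spring layout is deterministic, clamps fixed nodes, and balances forces", {
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a"), directed = FALSE)
  p1 <- layout_spring(g, k = 0.5, iterations = 30, seed = 7)
  p2 <- layout_spring(g, k = 0.5, iterations = 30, seed = 7)
  expect_identical(p1, p2)

  init <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, 1))
  pf <- layout_spring(g, k = 0.5, iterations = 30, seed = 7,
                      fixed = c("a", "b", "c"), initial = init)
  expect_identical(pf[c("a", "b", "c"), ], init[c("a", "b", "c"), ])

  expect_error(layout_spring(g, fixed = "zz", initial = init),
               class = "sm_argument_error")
  expect_error(layout_spring(g, fixed = "a"), class = "sm_argument_error")

  # two free nodes joined by one edge settle near separation k;
  # oracle: small-step force integration of the same force law
  pair <- igraph::make_graph(c("u", "v"), directed = FALSE)
  k <- 1
  pos <- rbind(u = c(0.2, 0.3), v = c(0.6, 0.4))
  for (step in 1:20000) {
    d <- pos["u", ] - pos["v", ]
    dist <- max(sqrt(sum(d^2)), 0.01)
    f <- (k^2 / dist - dist^2 / k) * d / dist    # repulsion - attraction
    pos["u", ] <- pos["u", ] + 1e-4 * f
    pos["v", ] <- pos["v", ] - 1e-4 * f
  }
  oracle_sep <- sqrt(sum((pos["u", ] - pos["v", ])^2))
  expect_equal(oracle_sep, k, tolerance = 1e-3)

  pl <- layout_spring(pair, k = k, iterations = 100, seed = 3)
  sep <- sqrt(sum((pl["u", ] - pl["v", ]) ^ 2))
  expect_gte(sep, 0.5 * k); expect_lte(sep, 1.5 * k)
})

test_that("the reference graph keeps landmarks fixed and out-degree clamped", {
  set.seed(41)
  mk <- c("DNA1", "DNA2", "Histone3", "CD3", "CD4", "CD8a", "CD20",
          "CD68", "GranzymeB", "Vimentin")
  n <- length(mk)
  M <- matrix(runif(n * n, 5, 80), n, n, dimnames = list(mk, mk))
  diag(M) <- 1
  ar <- setNames(runif(n, 0.05, 0.6), mk)
  cfg <- analysis_config()
  g <- build_reference_graph(M, ar, cfg)

  outdeg <- igraph::degree(g, mode = "out")
  expect_true(all(outdeg == min(5, n - 1)))

  # edge semantics: each target is among the source's 5 closest markers
  el <- igraph::as_edgelist(g)
  for (m in mk) {
    targets <- el[el[, 1] == m, 2]
    closest <- names(sort(M[m, setdiff(mk, m)]))[1:5]
    expect_setequal(targets, closest)
  }

  pos <- layout_reference(g, cfg, seed = 11)
  lm <- intersect(cfg$landmark_markers, mk)
  expect_identical(pos[lm, , drop = FALSE], landmark_circle_positions(lm))
  pos2 <- layout_reference(g, cfg, seed = 11)
  expect_identical(pos, pos2)

  # fewer than 6 markers: edges to all others
  small <- M[1:3, 1:3]
  cfg_small <- analysis_config(landmark_markers = "DNA1")
  gs <- build_reference_graph(small, ar[1:3], cfg_small)
  expect_true(all(igraph::degree(gs, mode = "out") == 2))

  expect_error(build_reference_graph(M[8:10, 8:10], ar[8:10], cfg),
               class = "sm_argument_error")   # landmarks absent
})

test_that("planted nearest partners appear among reference edge targets", {
  pp <- generate_point_pattern(80, 80, 8, jitter_sd = 0.5, seed = 31)
  set.seed(32)
  far <- lapply(1:5, function(i)
    point_set(paste0("F", i), cbind(runif(40, 0, 499), runif(40, 0, 499))))
  pts <- c(list(A = pp$a, B = pp$b), setNames(far, paste0("F", 1:5)))
  M <- marker_pair_distance_matrix(pts, k = 1)
  cfg <- analysis_config(landmark_markers = c("F1", "F2"))
  g <- build_reference_graph(M, setNames(rep(0.1, 7), names(pts)), cfg)
  el <- igraph::as_edgelist(g)
  expect_true("B" %in% el[el[, 1] == "A", 2])
})

test_that("graphs serialize to GraphML and JSON with their attributes", {
  M <- matrix(c(0, 5, 7, 5, 0, 9, 7, 9, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  g <- build_cluster_graph(M, mk_assignment(c(a = 1, b = 1, c = 1)),
                           c(a = .1, b = .2, c = .3), "intra")
  pos <- layout_spring(g, k = 0.3, iterations = 30, seed = 1)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_spatial_graph(g, gml, positions = pos)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(back)$name, c("a", "b", "c"))
  expect_equal(sort(igraph::E(back)$weight_um), c(5, 7, 9))

  js <- withr::local_tempfile(fileext = ".json")
  write_spatial_graph(g, js, format = "json", positions = pos)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_setequal(parsed$nodes$name, c("a", "b", "c"))
  expect_equal(nrow(parsed$edges), 3)
})

test_that("dot summaries normalize expression and fill pairwise proximity", {
  ph1 <- generate_phantom(two_region_spec(seed = 51))
  ph2 <- generate_phantom(two_region_spec(seed = 52))
  ds <- dot_summary(list(NT = list(cells = ph1$cells, mask = ph1$mask),
                         DT = list(cells = ph2$cells, mask = ph2$mask)))
  for (d in c("NT", "DT")) {
    e <- ds$expression[ds$expression$dataset == d, ]
    expect_equal(max(e$normalized_expression), 1)
    expect_true(all(e$cell_prevalence_area >= 0 & e$cell_prevalence_area <= 1))
  }
  expect_true(all(ds$pairwise$fraction_below_cutoff >= 0 &
                    ds$pairwise$fraction_below_cutoff <= 1, na.rm = TRUE))

  # single marker dataset: normalized expression is exactly 1
  df <- data.frame(cell_id = 1:4, centroid_row = 1:4, centroid_col = 1:4,
                   M = c(70, 80, 90, 100))
  one <- dot_summary(list(d1 = list(cells = cell_table(df), mask = NULL)))
  expect_equal(one$expression$normalized_expression, 1)
  expect_error(dot_summary(list()), class = "sm_argument_error")
})
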