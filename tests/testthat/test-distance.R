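test_that("single-pair distances follow the 3-4-5 triangle and clamp k", {
  q <- point_set("Q", rbind(c(0, 0)))
  r <- point_set("R", rbind(c(3, 4)))
  s <- knn_mean_distance(q, r, k = 1)
  expect_equal(s$mean_knn_distance_um, 5)
  expect_equal(s$k_used, 1)

  r4 <- point_set("R", rbind(c(1, 0), c(2, 0), c(3, 0), c(4, 0)))
  s4 <- knn_mean_distance(q, r4, k = 10)
  expect_equal(s4$k_used, 4)
  expect_equal(s4$mean_knn_distance_um, mean(1:4))

  half <- point_set("R", rbind(c(3, 4)), pixel_size_um = 0.5)
  qh <- point_set("Q", rbind(c(0, 0)), pixel_size_um = 0.5)
  expect_equal(knn_mean_distance(qh, half, 1)$mean_knn_distance_um, 2.5)

  expect_error(knn_mean_distance(q, point_set("E", matrix(0, 0, 2)), 1),
               class = "sm_empty_error")
})

test_that("k-NN means equal the brute-force sorted-pairwise oracle", {
  set.seed(101)
  for (rep in 1:5) {
    nq <- sample(50:300, 1); nr <- sample(50:300, 1)
    q <- point_set("Q", cbind(runif(nq, 0, 400), runif(nq, 0, 400)))
    r <- point_set("R", cbind(runif(nr, 0, 400), runif(nr, 0, 400)))
    for (k in c(1, 5, 10)) {
      expect_equal(knn_mean_distance(q, r, k)$mean_knn_distance_um,
                   brute_knn_mean_um(q$centroids, r$centroids, k),
                   tolerance = 1e-9)
    }
    # monotone non-decreasing in k
    means <- vapply(c(1, 5, 10), function(k)
      knn_mean_distance(q, r, k)$mean_knn_distance_um, numeric(1))
    expect_true(all(diff(means) >= -1e-12))
  }
})

test_that("self-distances exclude exact self-pairs", {
  set.seed(3)
  pts <- cbind(runif(30, 0, 100), runif(30, 0, 100))
  p <- point_set("M", pts)
  s <- knn_mean_distance(p, p, k = 1)
  expect_gt(s$mean_knn_distance_um, 0)
  expect_equal(s$mean_knn_distance_um,
               brute_knn_mean_um(pts, pts, 1, self_exclude = TRUE),
               tolerance = 1e-9)
})

test_that("distance summaries are invariant under rigid motion", {
  set.seed(11)
  q <- cbind(runif(80, 0, 200), runif(80, 0, 200))
  r <- cbind(runif(90, 0, 200), runif(90, 0, 200))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  move <- function(x) sweep(x %*% rot, 2, c(-31.5, 12.25), "+")
  for (k in c(1, 5)) {
    a <- knn_mean_distance(point_set("Q", q), point_set("R", r), k)
    b <- knn_mean_distance(point_set("Q", move(q)), point_set("R", move(r)), k)
    expect_equal(a$mean_knn_distance_um, b$mean_knn_distance_um, tolerance = 1e-9)
  }
})

test_that("the pairwise matrix is entrywise the oracle and flags empty markers", {
  set.seed(19)
  pts <- list(
    A = point_set("A", cbind(runif(50, 0, 300), runif(50, 0, 300))),
    B = point_set("B", cbind(runif(50, 0, 300), runif(50, 0, 300))),
    C = point_set("C", cbind(runif(50, 0, 300), runif(50, 0, 300))))
  M <- marker_pair_distance_matrix(pts, k = 5)
  for (i in names(pts)) for (j in names(pts))
    expect_equal(M[i, j],
                 brute_knn_mean_um(pts[[i]]$centroids, pts[[j]]$centroids, 5,
                                   self_exclude = (i == j)),
                 tolerance = 1e-9)

  pts$D <- point_set("D", matrix(0, 0, 2))
  M2 <- marker_pair_distance_matrix(pts, k = 5)
  expect_true(all(is.na(M2["D", ])))
  expect_true(all(is.na(M2[, "D"])))
  expect_error(marker_pair_distance_matrix(list(D = pts$D), k = 1),
               class = "sm_empty_error")

  coincident <- list(X = point_set("X", rbind(c(1, 1), c(5, 5))),
                     Y = point_set("Y", rbind(c(1, 1), c(5, 5))))
  Mc <- marker_pair_distance_matrix(coincident, k = 1)
  expect_equal(Mc["X", "Y"], 0)
  expect_equal(Mc["Y", "X"], 0)

  planted <- generate_point_pattern(100, 100, 10, jitter_sd = 0, seed = 2)
  Mp <- marker_pair_distance_matrix(list(A = planted$a, B = planted$b), k = 1)
  expect_lte(Mp["A", "B"], 10 + 1e-6)
})

test_that("intra and inter cluster summaries restrict to the right marker pairs", {
  M <- matrix(c(0, 1, 2, 3,
                1, 0, 4, 5,
                2, 4, 0, 6,
                3, 5, 6, 0), 4, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  one <- structure(c(a = 1L, b = 1L, c = 1L, d = 1L), K = 1L,
                   class = "cluster_assignment")
  expect_equal(nrow(intra_cluster_distances(M, one)), 6)     # complete edge set
  solo <- structure(c(a = 1L, b = 2L, c = 3L, d = 4L), K = 4L,
                    class = "cluster_assignment")
  expect_equal(nrow(intra_cluster_distances(M, solo)), 0)

  two <- structure(c(a = 1L, b = 1L, c = 2L, d = 2L), K = 2L,
                   class = "cluster_assignment")
  intra <- intra_cluster_distances(M, two)
  expect_setequal(paste(intra$m_i, intra$m_j), c("a b", "c d"))
  expect_equal(intra$distance_um[intra$m_i == "a"], 1)       # mean of both directions

  expect_equal(inter_cluster_distance(M, solo, 1, 2),
               mean(c(M["a", "b"], M["b", "a"])))             # singleton reduction
  expect_equal(inter_cluster_distance(M, two, 1, 2),
               mean(c(M["a", "c"], M["a", "d"], M["b", "c"], M["b", "d"],
                      M["c", "a"], M["d", "a"], M["c", "b"], M["d", "b"])))
  expect_error(inter_cluster_distance(M, two, 1, 1), class = "sm_argument_error")
  expect_error(inter_cluster_distance(M, two, 1, 9), class = "sm_argument_error")
})

test_that("phantom regions ~200 um apart yield a matching inter-cluster distance", {
  spec <- phantom_spec(
    image_size = c(400, 400),
    regions = list(region_disc(1, c(100, 100), 50), region_disc(2, c(300, 300), 50)),
    marker_profiles = list(A = list(baseline = 5, enrichment = c("1" = 150)),
                           B = list(baseline = 5, enrichment = c("2" = 150))),
    cell_density = 20, cell_radius_px = 3, seed = 13)
  ph <- generate_phantom(spec)
  pts <- points_by_marker(ph$cells)
  M <- marker_pair_distance_matrix(pts, k = 1)
  asg <- structure(c(A = 1L, B = 2L), K = 2L, class = "cluster_assignment")
  d <- inter_cluster_distance(M, asg, 1, 2)
  expect_gte(d, 150); expect_lte(d, 250)   # centers are ~283 um apart, discs 100 um wide
})

test_that("proximity fractions count nearest distances strictly below the cutoff", {
  q <- point_set("Q", rbind(c(0, 0), c(10, 0), c(100, 0)))
  r <- point_set("R", rbind(c(1, 0), c(12, 0), c(150, 0)))
  pf <- proximity_fraction(q, r, cutoff_um = 30)
  expect_equal(pf$fraction, 2 / 3)
  expect_equal(pf$mean_nn_distance_um, mean(c(1, 2, 50)))
  expect_equal(proximity_fraction(q, r, cutoff_um = 1e6)$fraction, 1)

  near <- generate_point_pattern(500, 500, 25, jitter_sd = 1, seed = 77)
  pf25 <- proximity_fraction(near$a, near$b, cutoff_um = 30)
  expect_gte(pf25$fraction, 0.99)
})
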