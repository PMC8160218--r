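test_that("quantify_cells computes unweighted centroids and pixel means", {
  px <- matrix(0, 3, 4)
  px[1, 1] <- 10; px[1, 3] <- 20          # cell 1 on pixels (0,0) and (0,2)
  px[3, 4] <- 7                            # cell 2 on pixel (2,3)
  labels <- matrix(0L, 3, 4)
  labels[1, 1] <- 1L; labels[1, 3] <- 1L; labels[3, 4] <- 2L
  st <- image_stack(list(marker_image(px, "M")))
  tab <- quantify_cells(st, label_mask(labels))
  expect_equal(tab$cell_id, c(1L, 2L))
  expect_equal(tab$centroid_row, c(0, 2))
  expect_equal(tab$centroid_col, c(1, 3))   # mean of cols 0 and 2
  expect_equal(tab$M, c(15, 7))
  expect_error(quantify_cells(st, label_mask(matrix(0L, 5, 5))),
               class = "sm_dim_error")
  empty <- quantify_cells(st, label_mask(matrix(0L, 3, 4)))
  expect_equal(nrow(empty), 0)
})

test_that("positivity uses a strict greater-than threshold", {
  df <- data.frame(cell_id = 1:2, centroid_row = c(0, 1), centroid_col = c(0, 1),
                   M = c(59, 61))
  pos <- call_positivity(cell_table(df))
  expect_equal(unname(pos$calls[, "M"]), c(FALSE, TRUE))
  zero <- call_positivity(cell_table(transform(df, M = c(0, 0))))
  expect_equal(zero$n_any_positive, 0)
})

test_that("percentage count follows its worked definition", {
  df <- data.frame(cell_id = 1:5, centroid_row = 0:4, centroid_col = 0:4,
                   A = c(100, 100, 0, 0, 0), B = c(0, 100, 100, 100, 0))
  pos <- call_positivity(cell_table(df))
  expect_equal(percentage_count(pos, "A"), 0.5)
  expect_equal(percentage_count(pos, "B"), 0.75)
  expect_lte(percentage_count(pos, "A"), 1)
  # no normalization across markers: fractions may sum above the max single one
  expect_gte(percentage_count(pos, "A") + percentage_count(pos, "B"),
             max(percentage_count(pos, "A"), percentage_count(pos, "B")))
  all_neg <- call_positivity(cell_table(transform(df, A = 0, B = 0)))
  expect_error(percentage_count(all_neg, "A"), class = "sm_undefined_error")
})

test_that("noise-free phantom positivity matches planted ground truth", {
  ph <- generate_phantom(two_region_spec(seed = 6))
  pos <- call_positivity(ph$cells)
  expect_identical(unname(pos$calls), unname(ph$truth$true_positivity))
  for (m in colnames(pos$calls))
    expect_equal(percentage_count(pos, m),
                 sum(ph$truth$true_positivity[, m]) /
                   sum(rowSums(ph$truth$true_positivity) > 0))
})

test_that("marker correlation handles exact, degenerate and planted cases", {
  base <- data.frame(cell_id = 1:50, centroid_row = 0, centroid_col = 0)
  x <- seq(0, 98, by = 2)
  lin <- cell_table(cbind(base, data.frame(A = x, B = 2 * x + 1)))
  expect_equal(marker_correlation(lin, "A", "B")$r, 1)
  anti <- cell_table(cbind(base, data.frame(A = x, B = max(x) - x)))
  expect_equal(marker_correlation(anti, "A", "B")$r, -1)
  flat <- cell_table(cbind(base, data.frame(A = x, B = rep(1, 50))))
  expect_error(marker_correlation(flat, "A", "B"), class = "sm_degenerate_error")

  # invariance under positive affine rescaling
  resc <- cell_table(cbind(base, data.frame(A = x, B = 3 * x + 7)))
  set.seed(1); noisy_b <- x + rnorm(50, sd = 10); noisy_b <- noisy_b - min(noisy_b)
  n1 <- cell_table(cbind(base, data.frame(A = x, B = noisy_b)))
  n2 <- cell_table(cbind(base, data.frame(A = 2 * x + 5, B = noisy_b * 4 + 1)))
  expect_equal(marker_correlation(n1, "A", "B")$r,
               marker_correlation(n2, "A", "B")$r, tolerance = 1e-12)

  # planted rho = 0.6, n = 10,000: r within Fisher sampling error
  set.seed(99)
  xx <- rnorm(10000); yy <- 0.6 * xx + sqrt(1 - 0.36) * rnorm(10000)
  big <- cell_table(data.frame(cell_id = 1:10000, centroid_row = 0,
                               centroid_col = 0,
                               A = xx - min(xx), B = yy - min(yy)))
  res <- marker_correlation(big, "A", "B")
  expect_gte(res$r, 0.58); expect_lte(res$r, 0.62)
  expect_equal(res$z_fisher, atanh(res$r))
})

test_that("Fisher Z comparison matches its closed form and is antisymmetric", {
  # frozen oracle: (atanh(.57199) - atanh(.24448)) / sqrt(2/56418)
  res <- compare_correlations_fisher(0.24448, 56421, 0.57199, 56421)
  expect_equal(abs(res$z_statistic), 67.3403758206416, tolerance = 1e-10)
  expect_lt(res$two_sided_p, 0.001)

  same <- compare_correlations_fisher(0.3, 100, 0.3, 500)
  expect_equal(same$z_statistic, 0)
  expect_equal(same$two_sided_p, 1)

  a <- compare_correlations_fisher(0.2, 120, 0.5, 340)
  b <- compare_correlations_fisher(0.5, 340, 0.2, 120)
  expect_equal(a$z_statistic, -b$z_statistic)
  expect_equal(a$two_sided_p, b$two_sided_p)
  expect_error(compare_correlations_fisher(0.2, 3, 0.5, 100),
               class = "sm_argument_error")
  expect_error(compare_correlations_fisher(1, 10, 0.5, 100),
               class = "sm_argument_error")
})

test_that("two-sample KS behaves at the identical, disjoint and shifted extremes", {
  x <- rnorm(200)
  same <- compare_distributions_ks(x, x)
  expect_equal(same$D_statistic, 0)
  expect_gte(same$two_sided_p, 0.999)

  disjoint <- compare_distributions_ks(1:100, 201:300)
  expect_equal(disjoint$D_statistic, 1)

  set.seed(17)
  shifted <- compare_distributions_ks(rnorm(5000), rnorm(5000, mean = 3))
  expect_gte(shifted$D_statistic, 0.8)   # analytic sup-difference approaches 0.866
  expect_lt(shifted$two_sided_p, 0.001)

  # oracle: D from hand-built ECDFs
  set.seed(2)
  a <- runif(40); b <- runif(60, 0.2, 1.4)
  grid <- sort(c(a, b))
  d_oracle <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(compare_distributions_ks(a, b)$D_statistic, d_oracle,
               tolerance = 1e-12)
  expect_error(compare_distributions_ks(numeric(0), 1:3),
               class = "sm_argument_error")
})

test_that("intensity summary flags 1.5 IQR outliers and excludes them from extremes", {
  mk_cells <- function(v) cell_table(data.frame(
    cell_id = seq_along(v), centroid_row = 0, centroid_col = 0, M = v))
  s <- intensity_summary(mk_cells(1:5), "M")
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)

  const <- intensity_summary(mk_cells(rep(7, 10)), "M")
  expect_equal(const$q3 - const$q1, 0)
  expect_length(const$outliers, 0)

  out <- intensity_summary(mk_cells(c(1:100, 1000)), "M")
  expect_equal(out$outliers, 1000)
  expect_equal(out$max, 100)
})
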