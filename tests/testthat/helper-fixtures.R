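# Shared fixtures: small phantoms and independent oracles used across tests.

# Two disjoint disc regions, two or three markers enriched per region,
# noise-free by default. Small enough for fast repeated generation.
two_region_spec <- function(seed = 1, markers_per_region = 2, noise = 0,
                            size = c(200, 200), density = 15) {
  mk1 <- paste0("A", seq_len(markers_per_region))
  mk2 <- paste0("B", seq_len(markers_per_region))
  profiles <- c(
    setNames(lapply(seq_along(mk1), function(i)
      list(baseline = 5, enrichment = c("1" = 150 - 10 * (i - 1)))), mk1),
    setNames(lapply(seq_along(mk2), function(i)
      list(baseline = 5, enrichment = c("2" = 150 - 10 * (i - 1)))), mk2))
  phantom_spec(
    image_size = size,
    regions = list(region_disc(1, c(size[1] * 0.3, size[2] * 0.3), size[1] * 0.22),
                   region_disc(2, c(size[1] * 0.7, size[2] * 0.7), size[1] * 0.22)),
    marker_profiles = profiles,
    cell_density = density, cell_radius_px = 3,
    intensity_noise_sd = noise, seed = seed)
}

# Independent brute-force oracle: full pairwise distance matrix, each row
# sorted, mean of the first k columns (in micrometers).
brute_knn_mean_um <- function(q, r, k, self_exclude = FALSE, pixel_size_um = 1) {
  total <- 0
  count <- 0
  for (i in seq_len(nrow(q))) {
    d <- sqrt((q[i, 1] - r[, 1])^2 + (q[i, 2] - r[, 2])^2)
    if (self_exclude) d <- d[-i]
    d <- sort(d)
    kk <- min(k, length(d))
    total <- total + sum(d[seq_len(kk)])
    count <- count + kk
  }
  total / count * pixel_size_um
}

# All set partitions of seq_len(n) (restricted growth strings), for the
# exhaustive k-means partition oracle on small marker sets.
all_partitions <- function(n, k) {
  res <- list()
  recurse <- function(assign, next_max) {
    i <- length(assign) + 1
    if (i > n) {
      if (max(assign) == k) res[[length(res) + 1]] <<- assign
      return()
    }
    for (g in seq_len(min(next_max, k)))
      recurse(c(assign, g), max(next_max, g + 1))
  }
  recurse(integer(0), 1)
  res
}

partition_sse <- function(X, assign) {
  sum(vapply(unique(assign), function(g) {
    rows <- X[assign == g, , drop = FALSE]
    ctr <- colMeans(rows)
    sum(sweep(rows, 2, ctr)^2)
  }, numeric(1)))
}
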