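# Support filter, single-linkage clustering with the dthresh cut, ranking
# and cell volumes, against O(n^2) and union-find oracles.

test_that("support filter keeps points with enough close neighbours", {
  cfg <- detection_config()
  # a lone point has no neighbours
  expect_equal(nrow(filter_supported_points(matrix(0, 1, 3), cfg)), 0)
  # interior points of a dense block at grid spacing have hundreds
  block <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 0.35
  kept <- filter_supported_points(block, cfg)
  expect_true(nrow(kept) > 0)
  centre <- matrix(rep(2 * 0.35, 3), 1)
  expect_true(any(rowSums(abs(sweep(kept, 2, centre))) < 1e-9))
})

test_that("support filter matches the O(n^2) neighbour-count oracle", {
  set.seed(11)
  pts <- matrix(runif(3 * 300, 0, 6), ncol = 3)
  cfg <- detection_config(nthresh = 4)
  kept <- filter_supported_points(pts, cfg)
  counts <- oracle_neighbor_counts(pts, cfg$neighbor_radius)
  expect_equal(nrow(kept), sum(counts >= 4))
  expect_true(all(kept %in% pts[counts >= 4, ]))
})

test_that("clusters join below dthresh and split above it", {
  cfg <- detection_config(mingroup = 7)
  blob <- function(center, n = 20) {
    set.seed(5)
    sweep(matrix(runif(3 * n, -0.8, 0.8), ncol = 3), 2, center, "+")
  }
  # six mutually close points: below mingroup, no site
  expect_length(cluster_sites(blob(c(0, 0, 0), 6), cfg), 0)
  # closest-point distance ~6 A: two sites
  two <- cluster_sites(rbind(blob(c(0, 0, 0)), blob(c(7.6, 0, 0))), cfg)
  expect_length(two, 2)
  # closest-point distance ~4 A: one site
  one <- cluster_sites(rbind(blob(c(0, 0, 0)), blob(c(5.6, 0, 0))), cfg)
  expect_length(one, 1)
})

test_that("clustering equals a union-find oracle on random instances", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(120, 300, 480)[seed]
    pts <- matrix(runif(3 * n, 0, 25), ncol = 3)
    labels <- flexsite:::cpp_cluster_threshold(pts, 5.0)
    oracle <- oracle_union_find(pts, 5.0)
    expect_equal(cluster_signature(labels), cluster_signature(oracle))
  }
})

test_that("site-point count is conserved across clustering", {
  set.seed(2)
  pts <- matrix(runif(3 * 200, 0, 15), ncol = 3)
  cfg <- detection_config(mingroup = 5)
  sites <- cluster_sites(pts, cfg)
  labels <- flexsite:::cpp_cluster_threshold(pts, cfg$dthresh)
  sizes <- table(labels)
  discarded <- sum(sizes[sizes < cfg$mingroup])
  expect_equal(sum(vapply(sites, function(s) s$n, numeric(1))) + discarded,
               nrow(pts))
})

test_that("ranking keeps the largest sites in deterministic order", {
  cfg <- detection_config(max_sites = 5)
  mk <- function(n, offset) flexsite:::new_site(
    matrix(runif(3 * n, 0, 2), ncol = 3) + offset, cfg)
  set.seed(3)
  sites <- lapply(c(30, 10, 25, 8, 12, 9, 40), function(n) mk(n, runif(1, 0, 50)))
  ranked <- rank_sites(sites, cfg)
  expect_length(ranked, 5)
  ns <- vapply(ranked, function(s) s$n, numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_equal(vapply(ranked, function(s) s$rank, numeric(1)), 1:5)
  # equal-n sites: order is stable across calls
  sites2 <- lapply(1:2, function(i) mk(10, i * 10))
  expect_identical(rank_sites(sites2, cfg), rank_sites(sites2, cfg))
})

test_that("volume counts distinct occupied grid cells", {
  cfg <- detection_config()
  one <- flexsite:::new_site(matrix(c(0.35, 0.7, 1.05), 1, 3), cfg)
  expect_equal(one$volume, 0.35^3, tolerance = 1e-12)
  block <- as.matrix(expand.grid(0:9, 0:9, 0:9)) * 0.35
  expect_equal(site_volume(flexsite:::new_site(block, cfg), cfg), 1000 * 0.35^3,
               tolerance = 1e-12)
  # duplicated points do not double-count cells
  dup <- rbind(block, block)
  expect_equal(site_volume(flexsite:::new_site(dup, cfg), cfg), 1000 * 0.35^3,
               tolerance = 1e-12)
})
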