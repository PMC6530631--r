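test_that("epsilon follows the compound-sphere closed form", {
  ## independent oracle: radius of a sphere with volume 1/density
  oracle <- function(density, r) (3 / (4 * pi * density))^(1 / 3) - r
  expect_equal(compute_epsilon(3.9e-3, 2.5), oracle(3.9e-3, 2.5))
  expect_equal(compute_epsilon(3.9e-3, 2.5), 1.4411, tolerance = 1e-4)
  expect_equal(compute_epsilon(9e-6, 8), 21.823, tolerance = 1e-3)
  ## compound radius equal to the soma radius -> configuration error
  d_crit <- 3 / (4 * pi * 8^3)
  expect_error(compute_epsilon(d_crit, 8), "too high")
})

test_that("sublayer planning tiles the layer bottom-up", {
  s <- plan_sublayers(150, 2.5)
  expect_equal(nrow(s), 20L)
  expect_equal(s$y_hi - s$y_lo, rep(7.5, 20))
  expect_equal(s$y_lo[1], 0)
  expect_equal(s$y_hi[20], 150)
  s <- plan_sublayers(150, 8, y_offset = 10)
  expect_equal(nrow(s), 6L)
  expect_equal(s$y_lo[1], 10)
  expect_error(plan_sublayers(5, 2.5), "below one sublayer")
})

test_that("random walk places non-overlapping somata inside the region", {
  set.seed(7)
  pts <- random_walk_place(100, 100, 30, 0, 400, 2.5,
                           compute_epsilon(3.9e-3, 2.5))
  expect_equal(nrow(pts), 400L)
  expect_true(all(pts[, "x"] >= 0 & pts[, "x"] <= 100))
  expect_true(all(pts[, "y"] >= 0 & pts[, "y"] < 30))
  expect_true(all(pts[, "z"] >= 0 & pts[, "z"] <= 100))
  expect_gte(min_pair_dist(pts), 5)          # brute-force all-pairs oracle
  set.seed(7)
  one <- random_walk_place(50, 50, 10, 0, 1, 2.5, 1.4)
  expect_equal(nrow(one), 1L)
})

test_that("an overfull region saturates with a warning and partial result", {
  set.seed(1)
  expect_warning(
    pts <- random_walk_place(20, 20, 8, 0, 500, 2.5, 0.5),
    "saturated")
  expect_lt(nrow(pts), 500L)
  expect_gte(min_pair_dist(pts), 5)
})

test_that("vertical coordinates are uniform within each sublayer", {
  set.seed(11)
  pts <- random_walk_place(200, 200, 7.5, 20, 800, 2.5, 1.44)
  expect_true(all(pts[, "y"] >= 20 & pts[, "y"] < 27.5))
  ## law of large numbers: empirical mean near the sublayer center
  expect_equal(mean(pts[, "y"]), 23.75, tolerance = 0.05)
})

test_that("Purkinje grid respects slab geometry and the reference count", {
  set.seed(3)
  pc <- place_purkinje(400, 400, 0.45e-3, 150, 180)
  expect_true(nrow(pc) >= 69 && nrow(pc) <= 72)
  expect_true(all(pc[, "y"] >= 150 & pc[, "y"] < 180))
  ## dendritic slabs (30 um thick in z) must not overlap: pairs are either
  ## in distinct rows (|dz| >= 30) or laterally separated in the same row
  dz <- abs(outer(pc[, "z"], pc[, "z"], "-"))
  dx <- abs(outer(pc[, "x"], pc[, "x"], "-"))
  same <- dz < 30 - 1e-9
  diag(same) <- FALSE
  expect_true(all(dx[same] >= 30))
  expect_gte(min_pair_dist(pc), 15)  # soma diameter
})

test_that("ascending-axon heights follow the truncated Gaussian", {
  cfg <- scaffold_config()
  set.seed(5)
  ## somata at the layer bottom: the pial cap (330 um) barely binds, so the
  ## sample mean and sd sit close to the nominal 181 +/- 66 um
  h0 <- sample_aa_heights(20000, soma_y = 0, cfg)
  expect_true(all(h0 > 0 & h0 <= 330))
  expect_equal(mean(h0), 181, tolerance = 0.02)
  expect_equal(sd(h0), 66, tolerance = 0.08)
  ## higher somata are truncated at the pia: tip = soma + height <= 330
  hy <- sample_aa_heights(5000, soma_y = 140, cfg)
  expect_true(all(hy <= 190))
  expect_identical(sample_aa_heights(0, numeric(0), cfg), numeric(0))
})

test_that("placement covers every type, layer containment and unique ids", {
  p <- fixture_placement()
  cfg <- fixture_config()
  lb <- layer_bounds(cfg)
  cells <- p$cells
  expect_setequal(unique(cells$type), cfg$neurons$name)
  expect_false(anyDuplicated(cells$cell_id) > 0)
  expect_equal(cells$cell_id, seq_len(nrow(cells)))
  for (i in seq_len(nrow(cfg$neurons))) {
    row <- cfg$neurons[i, ]
    b <- lb[[row$layer]]
    y <- cells$y[cells$type == row$name]
    expect_true(all(y >= b[1] & y <= b[2]), label = paste("layer", row$name))
  }
  ## every GrC has an aa height, also the pf vertical coordinate
  expect_setequal(p$aa$cell_id, cells$cell_id[cells$type == "GrC"])
  expect_true(all(p$aa$aa_height > 0))
})

test_that("per-population soma non-overlap holds in 3D (brute force)", {
  p <- fixture_placement()
  cfg <- fixture_config()
  for (nm in cfg$neurons$name) {
    m <- as.matrix(p$cells[p$cells$type == nm, c("x", "y", "z"), with = FALSE])
    r <- cfg$neurons$soma_radius[cfg$neurons$name == nm]
    if (nrow(m) > 4000) m <- m[sample(nrow(m), 4000), ]  # keeps O(n^2) sane
    expect_gte(min_pair_dist(m), 2 * r - 1e-9)
  }
})

test_that("density recovery: placed counts track expected counts over seeds", {
  cfg <- fixture_config()
  ec <- expected_counts(cfg)
  for (seed in c(1, 2, 3)) {
    p <- suppressWarnings(place_cells(cfg, seed = seed))
    n <- table(p$cells$type)
    for (nm in names(ec)) {
      tol <- if (nm == "GrC") 0.10 else 0.05
      ## the granule layer jams below its nominal density, as in the
      ## reference reconstruction (~6% shortfall at full scale)
      expect_lt(abs(n[[nm]] - ec[[nm]]) / max(ec[[nm]], 1), tol + 1e-9)
    }
  }
})

test_that("placement is deterministic under a fixed seed", {
  cfg <- fixture_config()
  p1 <- suppressWarnings(place_cells(cfg, seed = 9))
  p2 <- suppressWarnings(place_cells(cfg, seed = 9))
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$aa, p2$aa)
  p3 <- suppressWarnings(place_cells(cfg, seed = 10))
  expect_false(identical(p1$cells, p3$cells))
})

test_that("pairwise-distance KDE behaves as a density estimate", {
  ## two points at distance d: single maximum at d
  two <- rbind(c(0, 0, 0), c(30, 0, 0))
  k <- kde_pairwise_distances(two, bandwidth = 2)
  expect_length(k$maxima, 1L)
  expect_equal(k$maxima, 30, tolerance = 0.5)
  ## integrates to ~1 and matches a fine histogram
  set.seed(2)
  pts <- matrix(runif(600, 0, 100), ncol = 3)
  k <- kde_pairwise_distances(pts)
  expect_equal(sum(k$y) * diff(k$x[1:2]), 1, tolerance = 0.02)
  d <- as.numeric(dist(pts))
  h <- hist(d, breaks = 50, plot = FALSE)
  approx_dens <- approx(k$x, k$y, xout = h$mids)$y
  expect_gt(cor(h$density, approx_dens), 0.98)
  expect_error(kde_pairwise_distances(pts[1, , drop = FALSE]), "at least 2")
})

test_that("KDE is unimodal for walk-placed populations, multimodal for PCs", {
  p <- fixture_placement()
  m <- as.matrix(p$cells[p$cells$type == "GrC", c("x", "y", "z"), with = FALSE])
  set.seed(1)
  k <- kde_pairwise_distances(m, max_pairs = 2e5)
  expect_length(k$maxima, 1L)
  set.seed(4)
  pc <- place_purkinje(400, 400, 0.45e-3, 150, 180)
  k <- kde_pairwise_distances(pc)
  expect_gte(length(k$maxima), 3L)
})
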