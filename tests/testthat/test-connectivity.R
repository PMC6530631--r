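test_that("glomerulus-granule candidates are exactly the 40 um sphere", {
  cfg <- scaffold_config(scale = 0.25)
  cells <- data.frame(
    type = c("Glom", "Glom", "Glom", "GrC", "GrC"),
    x = c(10, 50, 90, 20, 85),
    y = c(10, 10, 10, 20, 15),
    z = c(10, 10, 10, 10, 10))
  p <- toy_placement(cells, cfg)
  ca <- geometric_candidates("glom_grc", p, cfg)
  ## brute-force oracle
  pos <- p$cells
  pairs <- expand.grid(pre = 1:3, post = 4:5)
  d <- sqrt((pos$x[pairs$pre] - pos$x[pairs$post])^2 +
            (pos$y[pairs$pre] - pos$y[pairs$post])^2 +
            (pos$z[pairs$pre] - pos$z[pairs$post])^2)
  want <- pairs[d <= 40, ]
  got <- data.frame(pre = ca$pre_id, post = ca$post_id)
  expect_setequal(paste(got$pre, got$post), paste(want$pre, want$post))
  ## a GrC with no glom within reach gets no invented edges
  lonely <- toy_placement(data.frame(type = c("Glom", "GrC"),
                                     x = c(0, 90), y = c(10, 10),
                                     z = c(0, 90)), cfg)
  expect_equal(nrow(geometric_candidates("glom_grc", lonely, cfg)), 0L)
})

test_that("geometry bounds are monotone: enlarging never loses candidates", {
  cfg <- fixture_config()
  p <- fixture_placement()
  ca40 <- geometric_candidates("glom_grc", p, cfg)
  cfg2 <- cfg
  cfg2$rules$glom_grc$geometry$max_dist <- 60
  ca60 <- geometric_candidates("glom_grc", p, cfg2)
  k40 <- paste(ca40$pre_id, ca40$post_id)
  k60 <- paste(ca60$pre_id, ca60$post_id)
  expect_true(all(k40 %in% k60))
  expect_gte(nrow(ca60), nrow(ca40))
})

test_that("symmetric rules exclude self-pairs", {
  cfg <- fixture_config()
  p <- fixture_placement()
  for (nm in c("goc_goc", "sc_sc", "bc_bc")) {
    ca <- geometric_candidates(nm, p, cfg)
    expect_true(all(ca$pre_id != ca$post_id), label = nm)
  }
})

test_that("pruning enforces exact convergence when candidates suffice", {
  cfg <- fixture_config()
  p <- fixture_placement()
  ca <- geometric_candidates("glom_grc", p, cfg)
  set.seed(1)
  e <- prune_candidates(ca, cfg$rules$glom_grc)
  n_cand <- table(ca$post_id)
  deg <- table(factor(e$post_id, levels = names(n_cand)))
  full <- n_cand >= 4
  expect_true(all(deg[full] == 4))
  expect_true(all(deg[!full] == n_cand[!full]))
  ## no duplicate pairs
  expect_false(anyDuplicated(paste(e$pre_id, e$post_id)) > 0)
})

test_that("pruning is the identity when candidates equal the target", {
  cfg <- scaffold_config(scale = 0.25)
  cells <- data.frame(type = c(rep("Glom", 4), "GrC"),
                      x = c(10, 20, 30, 25, 20),
                      y = c(5, 5, 5, 10, 8), z = rep(10, 5))
  p <- toy_placement(cells, cfg)
  ca <- geometric_candidates("glom_grc", p, cfg)
  expect_equal(nrow(ca), 4L)
  set.seed(1)
  e <- prune_candidates(ca, cfg$rules$glom_grc)
  expect_setequal(paste(e$pre_id, e$post_id), paste(ca$pre_id, ca$post_id))
})

test_that("distance-decay pruning prefers near partners", {
  ## one post cell, candidates on two shells; the near shell must dominate
  cfg <- scaffold_config(scale = 0.25)
  rule <- list(pre = "Glom", post = "GrC", conv = 10, div = NA,
               lambda = c(5, 5, 5))
  n <- 40
  cands <- data.table::data.table(
    pre_id = seq_len(2 * n), post_id = 1L,
    dx = c(rep(8, n), rep(35, n)), dy = 0, dz = 0,
    dist = c(rep(8, n), rep(35, n)))
  set.seed(2)
  e <- prune_candidates(cands, rule)
  expect_equal(nrow(e), 10L)
  expect_gte(mean(e$dist <= 8), 0.9)
})

test_that("GoC-GrC fusion equals the relational join with deduplication", {
  cfg <- scaffold_config(scale = 0.25)
  set.seed(8)
  cells <- data.frame(
    type = c(rep("GoC", 3), rep("Glom", 8), rep("GrC", 12)),
    x = runif(23, 0, 100), y = runif(23, 0, 100), z = runif(23, 0, 100))
  p <- toy_placement(cells, cfg)
  goc_glom <- data.table::data.table(
    pre_id = c(1L, 1L, 2L, 3L, 3L), post_id = c(4L, 5L, 5L, 6L, 7L),
    dist = 0)
  glom_grc <- data.table::data.table(
    pre_id = c(4L, 4L, 5L, 5L, 6L, 7L, 8L),
    post_id = c(12L, 13L, 13L, 14L, 15L, 15L, 16L), dist = 0)
  fused <- fuse_goc_glom_grc(goc_glom, glom_grc, p)
  ## brute-force relational join oracle
  want <- unique(merge(as.data.frame(goc_glom)[, 1:2],
                       as.data.frame(glom_grc)[, 1:2],
                       by.x = "post_id", by.y = "pre_id")[, c("pre_id", "post_id.y")])
  expect_setequal(paste(fused$pre_id, fused$post_id),
                  paste(want$pre_id, want$post_id.y))
  ## distances are GoC-GrC soma distances, recomputed
  pos <- p$cells
  d <- sqrt((pos$x[fused$pre_id] - pos$x[fused$post_id])^2 +
            (pos$y[fused$pre_id] - pos$y[fused$post_id])^2 +
            (pos$z[fused$pre_id] - pos$z[fused$post_id])^2)
  expect_equal(fused$dist, d, tolerance = 1e-12)
  ## g inhibits two gloms of the same GrC -> one edge
  expect_equal(sum(fused$pre_id == 1 & fused$post_id == 13), 1L)
})

test_that("connectome has referential integrity and consistent distances", {
  p <- fixture_placement()
  cn <- fixture_connectome()
  cfg <- fixture_config()
  pos <- p$cells
  type_of <- function(ids) pos$type[match(ids, pos$cell_id)]
  pre_of <- c(glom_grc = "Glom", glom_goc = "Glom", goc_grc = "GoC",
              goc_goc = "GoC", aa_goc = "GrC", pf_goc = "GrC", sc_sc = "SC",
              bc_bc = "BC", pf_sc = "GrC", pf_bc = "GrC", sc_pc = "SC",
              bc_pc = "BC", aa_pc = "GrC", pf_pc = "GrC", pc_dcnc = "PC",
              glom_dcnc = "Glom")
  for (nm in names(cn$edges)) {
    e <- cn$edges[[nm]]
    if (!nrow(e)) next
    expect_true(all(type_of(e$pre_id) == pre_of[[nm]]), label = paste(nm, "pre"))
    d <- sqrt((pos$x[e$pre_id] - pos$x[e$post_id])^2 +
              (pos$y[e$pre_id] - pos$y[e$post_id])^2 +
              (pos$z[e$pre_id] - pos$z[e$post_id])^2)
    expect_lt(max(abs(d - e$dist)), 1e-6)
    expect_false(anyDuplicated(paste(e$pre_id, e$post_id)) > 0, )
  }
})

test_that("connectome construction is deterministic under a fixed seed", {
  p <- fixture_placement()
  c1 <- build_connectome(p, seed = 5)
  c2 <- build_connectome(p, seed = 5)
  for (nm in names(c1$edges))
    expect_identical(c1$edges[[nm]], c2$edges[[nm]])
  c3 <- build_connectome(p, seed = 6)
  expect_false(identical(c1$edges$glom_grc, c3$edges$glom_grc))
})

test_that("missing populations are reported by rule", {
  p <- fixture_placement()
  p2 <- p
  p2$cells <- p$cells[p$cells$type != "PC", ]
  expect_error(build_connectome(p2, seed = 1), "PC")
})

test_that("ratio report recovers targets with a tight regression", {
  p <- fixture_placement()
  cn <- fixture_connectome()
  rr <- ratio_report(cn, p)
  expect_true(all(c("conv_mean", "div_mean", "conv_target") %in%
                  names(rr$ratios)))
  glom_grc <- rr$ratios[rr$ratios$connection == "glom_grc", ]
  expect_equal(glom_grc$conv_mean, 4, tolerance = 0.05)
  expect_gt(rr$regression$convergence$r2, 0.95)
  expect_true(rr$regression$convergence$slope > 0.85 &&
              rr$regression$convergence$slope < 1.1)
  ## degenerate regression is flagged, not fabricated
  one <- rr
  deg <- ratio_report(structure(list(edges = cn$edges["glom_grc"],
                                     goc_glom = cn$goc_glom[0, ],
                                     seed = 1, config = {
                                       cfg <- fixture_config()
                                       cfg$rules <- cfg$rules["glom_grc"]
                                       cfg
                                     }),
                                class = "scaffold_connectome"), p)
  expect_true(is.na(deg$regression$convergence$slope))
  expect_match(deg$regression$convergence$note, "degenerate")
})

test_that("orthogonal-plexus variant swaps the interneuron axon fields", {
  cfg <- scaffold_config(scale = 0.25, orthogonal_plexus = TRUE)
  base <- scaffold_config(scale = 0.25)
  expect_equal(cfg$rules$sc_pc$geometry, base$rules$bc_pc$geometry)
  expect_equal(cfg$rules$bc_pc$geometry, base$rules$sc_pc$geometry)
})
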