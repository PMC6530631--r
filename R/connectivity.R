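## Connectome construction: geometric candidate generation per connection
## type (intersection of axonal and dendritic fields), then pruning to the
## configured convergence/divergence targets with direction-specific
## distance-decay probabilities.

type_positions <- function(placement, type_name) {
  sel <- placement$cells$type == type_name
  placement$cells[sel, c("cell_id", "x", "y", "z"), with = FALSE]
}

grc_fibers <- function(placement) {
  g <- type_positions(placement, "GrC")
  g <- merge(g, placement$aa, by = "cell_id", sort = TRUE)
  g$tip_y <- g$y + g$aa_height   # aa tip = parallel-fiber height
  g
}

cand_table <- function(pre, post, keep, dist = NULL) {
  ## pre, post: row-aligned data.tables after an expansion; keep: logical
  out <- data.table::data.table(
    pre_id = pre$cell_id[keep], post_id = post$cell_id[keep],
    dx = pre$x[keep] - post$x[keep],
    dy = pre$y[keep] - post$y[keep],
    dz = pre$z[keep] - post$z[keep])
  out$dist <- if (is.null(dist)) sqrt(out$dx^2 + out$dy^2 + out$dz^2) else dist[keep]
  out
}

## Candidate pairs by per-post scan: for each post cell, vectorized predicate
## over all pre cells.  `pred(pre, post_row)` returns a logical vector.
scan_candidates <- function(pre, post, pred) {
  res <- vector("list", nrow(post))
  for (k in seq_len(nrow(post))) {
    p <- post[k, ]
    sel <- which(pred(pre, p))
    if (!length(sel)) next
    res[[k]] <- data.table::data.table(
      pre_id = pre$cell_id[sel], post_id = p$cell_id,
      dx = pre$x[sel] - p$x, dy = pre$y[sel] - p$y, dz = pre$z[sel] - p$z)
  }
  out <- data.table::rbindlist(res)
  if (!nrow(out))
    return(data.table::data.table(pre_id = integer(), post_id = integer(),
                                  dx = numeric(), dy = numeric(),
                                  dz = numeric(), dist = numeric()))
  out$dist <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  out
}

radius_candidates <- function(pre, post, radius, exclude_self = FALSE) {
  rp <- radius_pairs_cpp(as.matrix(pre[, c("x", "y", "z"), with = FALSE]),
                         as.matrix(post[, c("x", "y", "z"), with = FALSE]),
                         radius)
  out <- data.table::data.table(
    pre_id = pre$cell_id[rp$i], post_id = post$cell_id[rp$j],
    dx = pre$x[rp$i] - post$x[rp$j],
    dy = pre$y[rp$i] - post$y[rp$j],
    dz = pre$z[rp$i] - post$z[rp$j],
    dist = rp$dist)
  if (exclude_self) out <- out[out$pre_id != out$post_id, ]
  data.table::setorder(out, post_id, pre_id)
  out
}

#' Geometric candidate pairs for one connection type
#'
#' Applies the connection rule's geometry predicate (axonal field of the
#' pre-synaptic type intersecting the dendritic field of the post-synaptic
#' type) and returns every admissible (pre, post) pair.  Symmetric rules
#' (GoC-GoC, SC-SC, BC-BC) exclude self-pairs.  Parallel-fiber rules use the
#' ascending-axon tip height as the fiber's vertical coordinate and bound its
#' transversal reach by half the configured maximum fiber length per side.
#'
#' @param name Connection rule name (one of `names(cfg$rules)`).
#' @param placement A `scaffold_placement`.
#' @param cfg The `scaffold_config` (defaults to the placement's).
#' @return data.table with columns `pre_id`, `post_id`, `dx`, `dy`, `dz`,
#'   `dist` (3D inter-soma distance, um).
#' @export
geometric_candidates <- function(name, placement, cfg = placement$config) {
  rule <- cfg$rules[[name]]
  if (is.null(rule)) stop("unknown connection rule: ", name)
  lb <- layer_bounds(cfg)
  mol <- lb$molecular
  half_pf <- cfg$sim$pf_max_dz
  g <- rule$geometry

  switch(name,
    glom_grc = radius_candidates(type_positions(placement, "Glom"),
                                 type_positions(placement, "GrC"),
                                 g$max_dist),
    glom_goc = scan_candidates(
      type_positions(placement, "Glom"), type_positions(placement, "GoC"),
      function(pre, p) (pre$x - p$x)^2 + (pre$z - p$z)^2 <= g$radius_xz^2 &
                        pre$y <= p$y),
    goc_glom = scan_candidates(
      type_positions(placement, "GoC"), type_positions(placement, "Glom"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$z - p$z) <= g$half_z),
    goc_goc = radius_candidates(type_positions(placement, "GoC"),
                                type_positions(placement, "GoC"),
                                g$max_dist, exclude_self = TRUE),
    aa_goc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "GoC"),
      function(pre, p) (pre$x - p$x)^2 + (pre$z - p$z)^2 <= g$radius_xz^2 &
                        pre$tip_y >= p$y),
    pf_goc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "GoC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$z - p$z) <= half_pf &
                        pre$tip_y >= mol[1]),
    sc_sc = radius_candidates(type_positions(placement, "SC"),
                              type_positions(placement, "SC"),
                              g$max_dist, exclude_self = TRUE),
    bc_bc = radius_candidates(type_positions(placement, "BC"),
                              type_positions(placement, "BC"),
                              g$max_dist, exclude_self = TRUE),
    pf_sc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "SC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$tip_y - p$y) <= g$half_y &
                        abs(pre$z - p$z) <= half_pf),
    pf_bc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "BC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$tip_y - p$y) <= g$half_y &
                        abs(pre$z - p$z) <= half_pf),
    sc_pc = scan_candidates(
      type_positions(placement, "SC"), type_positions(placement, "PC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$z - p$z) <= g$half_z),
    bc_pc = scan_candidates(
      type_positions(placement, "BC"), type_positions(placement, "PC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$z - p$z) <= g$half_z),
    aa_pc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "PC"),
      function(pre, p) abs(pre$z - p$z) <= g$half_z &
                        abs(pre$x - p$x) <= g$half_x &
                        pre$tip_y >= mol[1]),
    pf_pc = scan_candidates(
      grc_fibers(placement), type_positions(placement, "PC"),
      function(pre, p) abs(pre$x - p$x) <= g$half_x &
                        abs(pre$z - p$z) <= half_pf &
                        pre$tip_y >= mol[1]),
    pc_dcnc = scan_candidates(
      type_positions(placement, "PC"), type_positions(placement, "DCNC"),
      function(pre, p) rep(TRUE, nrow(pre))),
    glom_dcnc = scan_candidates(
      type_positions(placement, "Glom"), type_positions(placement, "DCNC"),
      function(pre, p) rep(TRUE, nrow(pre))),
    stop("unknown connection rule: ", name)
  )
}

#' Prune candidate pairs to a convergence or divergence target
#'
#' Per post-synaptic cell (convergence) or pre-synaptic cell (divergence),
#' samples without replacement exactly `min(target, n_candidates)` partners
#' with probability proportional to
#' `exp(-(dx/lx)^2 - (dy/ly)^2 - (dz/lz)^2)` using the rule's per-axis decay
#' lengths (`lambda = NULL` gives distance-flat selection).  Sampling uses
#' exponential race keys, so results are reproducible under a fixed seed.
#' Rules with no target pass candidates through unchanged.
#'
#' @param cands Candidate table from [geometric_candidates()].
#' @param rule The rule entry from `cfg$rules`.
#' @return data.table with columns `pre_id`, `post_id`, `dist`.
#' @export
prune_candidates <- function(cands, rule) {
  side <- if (!is.na(rule$conv)) "post_id" else if (!is.na(rule$div)) "pre_id"
          else NA_character_
  if (is.na(side) || !nrow(cands))
    return(cands[, c("pre_id", "post_id", "dist"), with = FALSE])
  target <- if (side == "post_id") rule$conv else rule$div
  dt <- data.table::copy(cands)
  dt$w <- if (is.null(rule$lambda)) rep(1, nrow(dt)) else
    exp(-((dt$dx / rule$lambda[1])^2 +
          (dt$dy / rule$lambda[2])^2 +
          (dt$dz / rule$lambda[3])^2))
  other <- setdiff(c("pre_id", "post_id"), side)
  data.table::setorderv(dt, c(side, other))  # stable order for reproducibility
  dt$key <- rexp(nrow(dt)) / pmax(dt$w, 1e-300)
  data.table::setorderv(dt, c(side, "key"))
  .I <- NULL  # appease R CMD check
  idx <- dt[, list(row = .I[seq_len(min(target, .N))]), by = side]$row
  out <- dt[idx, c("pre_id", "post_id", "dist"), with = FALSE]
  data.table::setorder(out, post_id, pre_id)
  out
}

#' Fuse GoC-Glom and Glom-GrC into direct GoC-GrC edges
#'
#' A Golgi cell inhibits a granule cell when it inhibits at least one
#' glomerulus on that granule cell's dendrites; duplicate (GoC, GrC) pairs
#' collapse to a single edge and the distance is recomputed between the two
#' somata.
#'
#' @param goc_glom,glom_grc Edge tables (`pre_id`, `post_id`, `dist`).
#' @param placement A `scaffold_placement` (for the soma positions).
#' @return Edge table (`pre_id` GoC, `post_id` GrC, `dist`).
#' @export
fuse_goc_glom_grc <- function(goc_glom, glom_grc, placement) {
  m <- merge(goc_glom[, c("pre_id", "post_id"), with = FALSE],
             glom_grc[, c("pre_id", "post_id"), with = FALSE],
             by.x = "post_id", by.y = "pre_id",
             allow.cartesian = TRUE, sort = FALSE)
  out <- unique(data.table::data.table(pre_id = m$pre_id,
                                       post_id = m$post_id.y))
  pos <- placement$cells
  pre <- pos[match(out$pre_id, pos$cell_id), ]
  post <- pos[match(out$post_id, pos$cell_id), ]
  out$dist <- sqrt((pre$x - post$x)^2 + (pre$y - post$y)^2 +
                   (pre$z - post$z)^2)
  data.table::setorder(out, post_id, pre_id)
  out
}

#' Build the full 16-type connectome
#'
#' Runs geometric candidate generation and pruning for every connection rule
#' in dependency order (GoC-Glom before the GoC-GrC fusion).  Pruning
#' shortfalls (fewer candidates than the target, e.g. at volume borders) are
#' kept as-is and reported in the returned object.
#'
#' @param placement A `scaffold_placement`.
#' @param seed Integer master seed for the pruning draws.
#' @param cfg The `scaffold_config` (defaults to the placement's).
#' @return A `scaffold_connectome`: list with `edges` (named list of edge
#'   tables, one per synaptic connection type), `goc_glom` (the intermediate
#'   edge set), `seed` and `config`.
#' @export
build_connectome <- function(placement, seed = 1L, cfg = placement$config) {
  stopifnot(inherits(placement, "scaffold_placement"))
  for (tp in unique(vapply(cfg$rules, function(r) r$pre, "")))
    if (!any(placement$cells$type == tp))
      stop("placement has no cells of type ", tp,
           " required by the connection rules")
  set.seed(seed)
  rule_names <- names(cfg$rules)
  child <- sample.int(.Machine$integer.max, length(rule_names))
  names(child) <- rule_names

  edges <- list()
  for (nm in rule_names) {
    set.seed(child[[nm]])
    cands <- geometric_candidates(nm, placement, cfg)
    edges[[nm]] <- prune_candidates(cands, cfg$rules[[nm]])
  }
  goc_glom <- edges$goc_glom
  edges$goc_glom <- NULL
  edges$goc_grc <- fuse_goc_glom_grc(goc_glom, edges$glom_grc, placement)
  edges <- edges[cfg$synapses$connection]

  out <- list(edges = edges, goc_glom = goc_glom, seed = seed, config = cfg)
  class(out) <- "scaffold_connectome"
  out
}

#' @export
print.scaffold_connectome <- function(x, ...) {
  n <- vapply(x$edges, nrow, integer(1))
  cat("Scaffold connectome:", sum(n), "edges over", length(n),
      "connection types (seed", x$seed, ")\n")
  for (nm in names(n)) cat(sprintf("  %-10s %d\n", nm, n[[nm]]))
  invisible(x)
}

#' Convergence/divergence report
#'
#' Per connection type, the mean and sd of the in-degree over post-synaptic
#' cells (convergence) and of the out-degree over pre-synaptic cells
#' (divergence), alongside the configured targets, plus least-squares
#' regressions of achieved vs target values across connection types for both
#' axes.  Divergence targets, where not configured directly, are implied by
#' the convergence target and the population sizes.
#'
#' @param connectome A `scaffold_connectome`.
#' @param placement The `scaffold_placement` it was built from.
#' @return A `scaffold_ratio_report`: data.table `ratios` plus `regression`
#'   (list with slope, r2 for convergence and divergence).
#' @export
ratio_report <- function(connectome, placement) {
  cfg <- connectome$config
  n_of <- function(tp) sum(placement$cells$type == tp)
  rows <- list()
  for (nm in names(cfg$rules)) {
    rule <- cfg$rules[[nm]]
    e <- if (nm == "goc_glom") connectome$goc_glom else connectome$edges[[nm]]
    if (is.null(e)) next
    n_pre <- n_of(rule$pre); n_post <- n_of(rule$post)
    indeg <- tabulate(match(e$post_id,
                            sort(unique(placement$cells$cell_id[
                              placement$cells$type == rule$post]))), n_post)
    outdeg <- tabulate(match(e$pre_id,
                             sort(unique(placement$cells$cell_id[
                               placement$cells$type == rule$pre]))), n_pre)
    conv_target <- rule$conv
    div_target <- if (!is.na(rule$div)) rule$div else
      if (!is.na(rule$conv)) rule$conv * n_post / n_pre else NA_real_
    if (is.na(conv_target) && !is.na(rule$div))
      conv_target <- rule$div * n_pre / n_post
    rows[[nm]] <- data.table::data.table(
      connection = nm,
      conv_mean = mean(indeg), conv_sd = sd(indeg), conv_target = conv_target,
      div_mean = mean(outdeg), div_sd = sd(outdeg), div_target = div_target,
      mean_dist = if (nrow(e)) mean(e$dist) else NA_real_,
      n_edges = nrow(e))
  }
  ratios <- data.table::rbindlist(rows)

  regress <- function(model, target) {
    ok <- is.finite(model) & is.finite(target)
    if (sum(ok) < 2 || sd(target[ok]) == 0)
      return(list(slope = NA_real_, r2 = NA_real_,
                  note = "degenerate regression: < 2 distinct targets"))
    fit <- lm(model[ok] ~ target[ok])
    list(slope = unname(coef(fit)[2]),
         r2 = summary(fit)$r.squared, note = NULL)
  }
  out <- list(
    ratios = ratios,
    regression = list(
      convergence = regress(ratios$conv_mean, ratios$conv_target),
      divergence  = regress(ratios$div_mean, ratios$div_target)))
  class(out) <- "scaffold_ratio_report"
  out
}

#' @export
print.scaffold_ratio_report <- function(x, ...) {
  print(x$ratios[, c("connection", "conv_mean", "conv_target",
                     "div_mean", "div_target", "mean_dist", "n_edges"),
                 with = FALSE], digits = 3)
  r <- x$regression
  cat(sprintf("convergence regression: slope %.3f, r2 %.3f\n",
              r$convergence$slope, r$convergence$r2))
  cat(sprintf("divergence  regression: slope %.3f, r2 %.3f\n",
              r$divergence$slope, r$divergence$r2))
  invisible(x)
}
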