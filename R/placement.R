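## Cell placement: bounded self-avoiding random walk for GrC/GoC/Glom/SC/BC,
## planar grid for PCs, rejection sampling for the 12 DCN cells.

#' Mean free spacing between somata at a given density
#'
#' Each cell notionally owns a compound sphere of volume `1/density`; the
#' scatter term epsilon is the difference between that sphere's radius and the
#' soma radius.  The random walk advances by one soma diameter plus a draw
#' around epsilon, which fills the volume without clustering.
#'
#' @param density Cells per um^3.
#' @param soma_radius Soma radius in um.
#' @return Epsilon in um.  Errors if the density is too high for the soma
#'   size (epsilon would be non-positive).
#' @examples
#' compute_epsilon(3.9e-3, 2.5)  # ~1.44 um for granule cells
#' @export
compute_epsilon <- function(density, soma_radius) {
  stopifnot(density > 0, soma_radius > 0)
  eps <- (3 / (4 * pi * density))^(1 / 3) - soma_radius
  if (eps <= 0)
    stop("density ", density, " too high for soma radius ", soma_radius,
         " (epsilon = ", signif(eps, 3), " um)")
  eps
}

#' Plan the sublayers for a population
#'
#' The walk operates in thin horizontal sublayers of height 1.5 soma
#' diameters (3 r), stacked bottom-up; only full sublayers are kept.
#'
#' @param layer_height Height of the layer in um.
#' @param soma_radius Soma radius in um.
#' @param y_offset Absolute y of the layer bottom (default 0).
#' @return Data frame with columns `y_lo`, `y_hi`, one row per sublayer.
#' @export
plan_sublayers <- function(layer_height, soma_radius, y_offset = 0) {
  h <- 3 * soma_radius
  n <- floor(layer_height / h)
  if (n < 1)
    stop("layer height ", layer_height, " um is below one sublayer (", h, " um)")
  data.frame(y_lo = y_offset + (seq_len(n) - 1) * h,
             y_hi = y_offset + seq_len(n) * h)
}

## Split a total count as evenly as possible over k sublayers.
split_count <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Place one population with the bounded self-avoiding random walk
#'
#' @param base_x,base_z Base rectangle in um.
#' @param layer_height Layer height in um.
#' @param y_offset Absolute y of the layer bottom.
#' @param n_target Total cells to place.
#' @param soma_radius Soma radius in um.
#' @param epsilon Scatter term from [compute_epsilon()].
#' @param max_tries Candidate redraws before a walk restart (default 200).
#' @param max_restarts Consecutive failed restarts per sublayer before
#'   declaring saturation (default 2000); the dense granule-cell layer jams
#'   close to its random-packing limit under this budget.
#' @param segment_max Accepted placements per walk segment before the walk
#'   restarts from a fresh uniform point (default 10).  Finite segments with
#'   uniformly scattered origins give uniform occupancy of the layer even
#'   for sparse populations, whose unbroken walks would diffuse into local
#'   clouds.
#' @return Matrix (n, 3) of soma centers `(x, y, z)`.  If a sublayer
#'   saturates the achieved count is smaller than `n_target` and a warning
#'   reports it.
#' @export
random_walk_place <- function(base_x, base_z, layer_height, y_offset,
                              n_target, soma_radius, epsilon,
                              max_tries = 200L, max_restarts = 2000L,
                              segment_max = 10L) {
  if (n_target == 0L)
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  subs <- plan_sublayers(layer_height, soma_radius, y_offset)
  per <- split_count(as.integer(n_target), nrow(subs))
  pts <- walk_place_cpp(base_x, base_z, subs$y_lo, subs$y_hi, per,
                        soma_radius, epsilon,
                        as.integer(max_tries), as.integer(max_restarts),
                        as.integer(segment_max))
  colnames(pts) <- c("x", "y", "z")
  if (nrow(pts) < n_target)
    warning(sprintf("placement saturated: %d of %d cells placed",
                    nrow(pts), n_target), call. = FALSE)
  pts
}

#' Place Purkinje cells on a staggered planar grid
#'
#' PC somata sit in a single plane between the granular and molecular layers.
#' Their flat dendritic slabs (radius ~150 um in x, 30 um thick in z) must
#' not overlap, so somata are arranged in rows along x at a z pitch of one
#' slab width; the x pitch follows from the planar density.  Alternate rows
#' are offset in x so that the offset/row-spacing angle averages about 5
#' degrees, with additional per-cell jitter, and a small y noise keeps the
#' layer from being perfectly planar.
#'
#' @param base_x,base_z Base rectangle in um.
#' @param planar_density Cells per um^2.
#' @param y_lo,y_hi Vertical extent of the PC layer.
#' @param slab_width Dendritic slab thickness in z (um, default 30).
#' @return Matrix (n, 3) of soma centers.
#' @export
place_purkinje <- function(base_x, base_z, planar_density, y_lo, y_hi,
                           slab_width = 30) {
  n_rows <- max(1L, floor(base_z / slab_width))
  ## rows in z at one slab-width pitch so adjacent slabs abut without
  ## overlapping; centered in the base
  z_rows <- (seq_len(n_rows) - 0.5) * slab_width +
    (base_z - n_rows * slab_width) / 2
  ## x pitch from the planar density at the given row spacing; alternate
  ## rows staggered by half a pitch (quincunx); per-cell jitter realizes the
  ## ~5 degree angular scatter between adjacent cells
  pitch <- 1 / (planar_density * slab_width)
  x0 <- (base_x - pitch * floor(base_x / pitch)) / 2
  jitter_sd <- slab_width * tan(5 * pi / 180)
  pts <- vector("list", n_rows)
  for (r in seq_len(n_rows)) {
    phase <- x0 + (r %% 2L) * pitch / 2
    if (phase > base_x - 1e-9) next
    x <- seq(phase, base_x - 1e-9, by = pitch)
    x <- pmin(pmax(x + rnorm(length(x), 0, jitter_sd), 0), base_x)
    y <- runif(length(x), y_lo, y_hi)
    pts[[r]] <- cbind(x = x, y = y, z = rep(z_rows[r], length(x)))
  }
  out <- do.call(rbind, pts)
  rownames(out) <- NULL
  out
}

#' Place DCN cells by rejection sampling
#'
#' Uniform random positions in the DCN block with soma non-overlap; at the
#' reference density this is 12 cells in 200 x 200 x 600 um^3, where a
#' random walk is unnecessary.
#'
#' @param cfg A `scaffold_config`.
#' @param n_target Number of cells.
#' @param soma_radius Soma radius in um.
#' @return Matrix (n, 3) of soma centers; x and z are centered under the
#'   cortical base, y is negative (below the cortex).
#' @export
place_dcn <- function(cfg, n_target, soma_radius) {
  v <- cfg$volume
  x0 <- (v$base_x - v$dcn_base_x) / 2
  z0 <- (v$base_z - v$dcn_base_z) / 2
  pts <- matrix(NA_real_, n_target, 3, dimnames = list(NULL, c("x", "y", "z")))
  n <- 0L
  for (it in seq_len(1000L * max(n_target, 1L))) {
    if (n >= n_target) break
    p <- c(x0 + runif(1) * v$dcn_base_x,
           -runif(1) * v$dcn_height,
           z0 + runif(1) * v$dcn_base_z)
    if (n == 0L ||
        min(sqrt(colSums((t(pts[seq_len(n), , drop = FALSE]) - p)^2))) >=
          2 * soma_radius) {
      n <- n + 1L
      pts[n, ] <- p
    }
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Sample ascending-axon heights
#'
#' Heights are Gaussian (181 +/- 66 um by default), measured upward from the
#' GrC soma, truncated below at a small positive value and above at the pial
#' surface (top of the molecular layer); the resulting tip height is also the
#' vertical coordinate of the cell's parallel fiber.
#'
#' @param n Number of heights.
#' @param soma_y Vector of GrC soma y coordinates (recycled to length `n`).
#' @param cfg A `scaffold_config` (for the distribution and the pia height).
#' @return Numeric vector of heights (um, from the soma).
#' @export
sample_aa_heights <- function(n, soma_y, cfg) {
  if (n == 0L) return(numeric(0))
  soma_y <- rep_len(soma_y, n)
  top <- sum(unlist(cfg$volume[c("granular_height", "pc_layer_height",
                                 "molecular_height")]))
  h <- rnorm(n, cfg$aa$mean, cfg$aa$sd)
  bad <- which(h <= 0)
  for (it in 1:100) {
    if (!length(bad)) break
    h[bad] <- rnorm(length(bad), cfg$aa$mean, cfg$aa$sd)
    bad <- bad[h[bad] <= 0]
  }
  if (length(bad)) h[bad] <- cfg$aa$mean
  pmin(h, top - soma_y)  # truncate at the pia
}

#' Place all seven cell types
#'
#' Runs the full placement stage: random-walk placement for GoC, Glom, GrC,
#' BC and SC in their layers, the planar grid for PCs, rejection sampling for
#' DCN cells, and ascending-axon height assignment for every GrC.  One master
#' seed expands into independent per-population child seeds.
#'
#' @param cfg A `scaffold_config`.
#' @param seed Integer master seed.
#' @return A `scaffold_placement`: list with `cells` (data.table with columns
#'   `cell_id`, `type_code`, `type`, `x`, `y`, `z`), `aa` (data.table
#'   `cell_id`, `aa_height`), the `seed` and the `config`.
#' @examples
#' p <- place_cells(scaffold_config(scale = 0.25), seed = 1)
#' table(p$cells$type)
#' @export
place_cells <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "scaffold_config"))
  set.seed(seed)
  child <- sample.int(.Machine$integer.max, nrow(cfg$neurons) + 1L)
  lb <- layer_bounds(cfg)
  targets <- expected_counts(cfg)
  v <- cfg$volume

  place_one <- function(i) {
    row <- cfg$neurons[i, ]
    set.seed(child[i])
    if (row$layer == "pc") {
      pc <- lb$pc
      place_purkinje(v$base_x, v$base_z, row$density, pc[1], pc[2],
                     slab_width = v$pc_layer_height)
    } else if (row$layer == "dcn") {
      place_dcn(cfg, targets[[row$name]], row$soma_radius)
    } else {
      b <- lb[[row$layer]]
      if (targets[[row$name]] == 0L)
        return(matrix(numeric(0), ncol = 3))
      random_walk_place(v$base_x, v$base_z, diff(b), b[1],
                        targets[[row$name]], row$soma_radius,
                        compute_epsilon(row$density, row$soma_radius))
    }
  }

  pops <- lapply(seq_len(nrow(cfg$neurons)), place_one)
  n_per <- vapply(pops, nrow, integer(1))
  cells <- data.table::data.table(
    cell_id   = seq_len(sum(n_per)),
    type_code = rep(cfg$neurons$type_code, n_per),
    type      = rep(cfg$neurons$name, n_per),
    x = unlist(lapply(pops, function(p) p[, 1])),
    y = unlist(lapply(pops, function(p) p[, 2])),
    z = unlist(lapply(pops, function(p) p[, 3]))
  )

  grc <- cells[cells$type == "GrC", ]
  set.seed(child[nrow(cfg$neurons) + 1L])
  aa <- data.table::data.table(
    cell_id = grc$cell_id,
    aa_height = sample_aa_heights(nrow(grc), grc$y, cfg)
  )

  out <- list(cells = cells, aa = aa, seed = seed, config = cfg)
  class(out) <- "scaffold_placement"
  out
}

#' @export
print.scaffold_placement <- function(x, ...) {
  cat("Scaffold placement:", nrow(x$cells), "cells (seed", x$seed, ")\n")
  print(x$cells[, .N, by = "type"])
  invisible(x)
}

#' Pairwise-distance kernel density estimate
#'
#' Gaussian KDE of the 3D pairwise inter-soma distances of one population,
#' with a fixed per-population bandwidth (Sheather-Jones plug-in by
#' default).  Homogeneous placements give a single maximum; the PC grid
#' gives several.  Maxima are filtered for prominence (2% of the peak
#' density) to suppress sampling wiggles on flat density tops.
#'
#' @param positions Matrix (n, 3) of soma centers, n >= 2.
#' @param bandwidth Kernel bandwidth in um, or `NULL` for the
#'   Sheather-Jones plug-in estimate.
#' @param max_pairs Upper bound on the number of pairwise distances used;
#'   larger populations are represented by a uniform random subsample of
#'   pairs (seeded by the caller).
#' @return List of class `scaffold_kde`: `x` (grid, um), `y` (density),
#'   `maxima` (positions of local maxima, increasing x), `bandwidth`.
#' @export
kde_pairwise_distances <- function(positions, bandwidth = NULL,
                                   max_pairs = 2e6) {
  n <- nrow(positions)
  if (is.null(n) || n < 2) stop("need at least 2 positions for a pairwise KDE")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    d <- dist(positions)
  } else {
    ## uniform subsample of pairs
    m <- as.integer(max_pairs)
    i <- sample.int(n, m, replace = TRUE)
    j <- sample.int(n - 1L, m, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)
    d <- sqrt((positions[i, 1] - positions[j, 1])^2 +
              (positions[i, 2] - positions[j, 2])^2 +
              (positions[i, 3] - positions[j, 3])^2)
  }
  d <- as.numeric(d)
  if (is.null(bandwidth)) {
    ## fixed per-population bandwidth by the Sheather-Jones plug-in rule,
    ## estimated on a bounded subsample of distances: resolves the
    ## multimodal lattice structure of the PC population while remaining
    ## smooth for the homogeneous ones
    bd <- if (length(d) > 5e4) d[sample.int(length(d), 5e4)] else d
    bandwidth <- stats::bw.SJ(bd)
  }
  dens <- density(d, bw = bandwidth)
  y <- dens$y
  k <- seq(2, length(y) - 1)
  loc <- k[y[k] > y[k - 1] & y[k] >= y[k + 1]]
  ## keep only prominent maxima: a peak must rise at least 2% of the global
  ## maximum above the deepest valley separating it from a higher peak
  if (length(loc) > 1) {
    keep <- logical(length(loc))
    for (m in seq_along(loc)) {
      hi <- loc[y[loc] > y[loc[m]]]
      if (!length(hi)) { keep[m] <- TRUE; next }
      saddle <- -Inf
      left <- hi[hi < loc[m]]; right <- hi[hi > loc[m]]
      if (length(left)) saddle <- max(saddle, min(y[max(left):loc[m]]))
      if (length(right)) saddle <- max(saddle, min(y[loc[m]:min(right)]))
      keep[m] <- (y[loc[m]] - saddle) >= 0.02 * max(y)
    }
    loc <- loc[keep]
  }
  out <- list(x = dens$x, y = y, maxima = dens$x[loc], bandwidth = dens$bw)
  class(out) <- "scaffold_kde"
  out
}

#' @export
print.scaffold_kde <- function(x, ...) {
  cat("Pairwise-distance KDE: bandwidth", signif(x$bandwidth, 4),
      "um; local maxima at", paste(signif(x$maxima, 4), collapse = ", "),
      "um\n")
  invisible(x)
}

#' @export
plot.scaffold_kde <- function(x, ...) {
  plot(x$x, x$y, type = "l", xlab = "pairwise distance (um)",
       ylab = "density", ...)
  abline(v = x$maxima, lty = 3)
  invisible(x)
}
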