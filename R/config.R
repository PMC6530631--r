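## Reference configuration: volumes, densities, LIF tables, synapse tables,
## connection rules.  All downstream stages read only from this object.

#' Reference scaffold configuration
#'
#' Returns the full configuration bundle for the reference cerebellar volume:
#' a 400 x 400 um^2 cortical base with 330 um height (granular 150 um,
#' Purkinje-cell layer 30 um, molecular 150 um) plus a 200 x 200 x 600 um^3
#' deep-cerebellar-nuclei (DCN) block, the seven neuron types with their
#' densities and soma radii, the per-type leaky integrate-and-fire (LIF)
#' parameters, the sixteen synaptic connection types (weight in nS, signed;
#' delay in ms), and the geometric/statistical connection rules used to build
#' the connectome.
#'
#' @param scale Linear scale factor applied to the cortical and DCN base
#'   dimensions (heights and densities are kept).  `scale = 1` is the
#'   reference volume; `scale = 0.25` gives a 100 x 100 um^2 cortical base
#'   used for fast tests.
#' @param orthogonal_plexus If `TRUE`, swap the stellate- and basket-cell
#'   axonal plexus orientations (on-beam vs off-beam) for the molecular-layer
#'   connectivity experiment.
#' @return A list of class `scaffold_config` with elements `volume`,
#'   `neurons`, `lif`, `synapses`, `rules`, `sim`, `aa` and
#'   `orthogonal_plexus`.
#' @examples
#' cfg <- scaffold_config()
#' subset(cfg$neurons, name == "GrC")
#' @export
scaffold_config <- function(scale = 1, orthogonal_plexus = FALSE) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0, scale <= 1)

  volume <- list(
    base_x           = 400 * scale,
    base_z           = 400 * scale,
    granular_height  = 150,
    pc_layer_height  = 30,
    molecular_height = 150,
    dcn_base_x       = 200 * scale,
    dcn_base_z       = 200 * scale,
    dcn_height       = 600
  )

  ## Densities in cells/um^3 (PC: planar, cells/um^2).
  neurons <- data.frame(
    name        = c("GoC", "Glom", "GrC", "PC", "BC", "SC", "DCNC"),
    type_code   = 1:7,
    soma_radius = c(8, 1.5, 2.5, 7.5, 6, 4, 10),
    density     = c(9e-6, 3e-4, 3.9e-3, 0.45e-3, 0.5e-4, 0.5e-4, 5e-7),
    layer       = c("granular", "granular", "granular", "pc",
                    "molecular_lower", "molecular_upper", "dcn"),
    is_parrot   = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )

  ## Per-type LIF parameters; glomeruli are parrot relays and carry none.
  lif <- data.frame(
    name    = c("GoC", "GrC", "PC", "BC", "SC", "DCNC"),
    C_m     = c(76, 3, 620, 14.6, 14.6, 89),      # pF
    tau_m   = c(21, 2, 88, 14.6, 14.6, 57),       # ms
    E_L     = c(-65, -74, -62, -68, -68, -59),    # mV
    t_ref   = c(2, 1.5, 0.8, 1.6, 1.6, 3.7),      # ms
    I_e     = c(36.8, 0, 600, 15.6, 15.6, 55.8),  # pA
    V_r     = c(-75, -84, -72, -78, -78, -69),    # mV
    V_th    = c(-55, -42, -47, -53, -53, -48),    # mV
    tau_exc = c(0.5, 0.5, 0.5, 0.64, 0.64, 7.1),  # ms
    tau_inh = c(10, 10, 1.6, 2, 2, 13.6),         # ms
    stringsAsFactors = FALSE
  )

  ## Sixteen connection types: weight (nS, signed: negative = inhibitory
  ## channel on the target) and delay (ms).
  synapses <- data.frame(
    connection = c("glom_grc", "glom_goc", "goc_grc", "goc_goc", "aa_goc",
                   "pf_goc", "sc_sc", "bc_bc", "pf_sc", "pf_bc", "sc_pc",
                   "bc_pc", "aa_pc", "pf_pc", "pc_dcnc", "glom_dcnc"),
    weight = c(9.0, 2.0, -5.0, -8.0, 20.0, 0.4, -2.0, -2.5, 0.2, 0.2,
               -8.5, -9.0, 75.0, 0.02, -0.0075, 0.006),
    delay  = c(4.0, 4.0, 2.0, 1.0, 2.0, 5.0, 1.0, 1.0, 5.0, 5.0,
               5.0, 4.0, 2.0, 5.0, 4.0, 4.0),
    stringsAsFactors = FALSE
  )

  rules <- default_rules(orthogonal_plexus)

  sim <- list(
    dt        = 0.1,   # ms
    E_exc     = 0,     # mV
    E_inh     = -85,   # mV
    pf_max_dz = 200    # half of the 400 um parallel-fiber length bound
  )

  ## Ascending-axon height distribution (um, measured up from the GrC soma).
  aa <- list(mean = 181, sd = 66)

  cfg <- list(volume = volume, neurons = neurons, lif = lif,
              synapses = synapses, rules = rules, sim = sim, aa = aa,
              orthogonal_plexus = orthogonal_plexus)
  class(cfg) <- "scaffold_config"
  validate_config(cfg)
  cfg
}

## Geometric + statistical rules for each connection type.  `conv` is the
## target mean number of afferents per post-synaptic cell, `div` the target
## efferents per pre-synaptic cell; NA means unconstrained.  `lambda` gives
## per-axis decay lengths (um) of the anisotropic Gaussian pruning kernel;
## NULL means distance-flat pruning.  Targets for the rules whose ratios are
## not printed anywhere are configuration values (see the methods vignette).
default_rules <- function(orthogonal_plexus = FALSE) {
  sc_axon <- list(half_x = 30, half_z = 150)   # on-beam (transversal)
  bc_axon <- list(half_x = 150, half_z = 30)   # off-beam (sagittal)
  if (orthogonal_plexus) { tmp <- sc_axon; sc_axon <- bc_axon; bc_axon <- tmp }

  list(
    glom_grc  = list(pre = "Glom", post = "GrC",
                     geometry = list(max_dist = 40),
                     conv = 4, div = NA_real_, lambda = c(10, 10, 10)),
    glom_goc  = list(pre = "Glom", post = "GoC",
                     geometry = list(radius_xz = 50),   # basolateral cylinder
                     conv = 20, div = NA_real_, lambda = c(50, 150, 50)),
    goc_glom  = list(pre = "GoC", post = "Glom",
                     geometry = list(half_x = 160, half_z = 160),  # axon box
                     conv = NA_real_, div = 20, lambda = c(160, 150, 160)),
    goc_goc   = list(pre = "GoC", post = "GoC",
                     geometry = list(max_dist = 160),
                     conv = 10, div = NA_real_, lambda = c(160, 160, 160)),
    aa_goc    = list(pre = "GrC", post = "GoC",
                     geometry = list(radius_xz = 50),
                     conv = 150, div = NA_real_, lambda = c(50, 150, 50)),
    pf_goc    = list(pre = "GrC", post = "GoC",
                     geometry = list(half_x = 100),     # apical cylinder
                     conv = 1200, div = NA_real_, lambda = c(100, 150, 200)),
    sc_sc     = list(pre = "SC", post = "SC",
                     geometry = list(max_dist = 100),
                     conv = 4, div = NA_real_, lambda = c(100, 100, 100)),
    bc_bc     = list(pre = "BC", post = "BC",
                     geometry = list(max_dist = 100),
                     conv = 4, div = NA_real_, lambda = c(100, 100, 100)),
    pf_sc     = list(pre = "GrC", post = "SC",
                     geometry = list(half_x = 15, half_y = 15),
                     conv = 600, div = NA_real_, lambda = c(15, 15, 200)),
    pf_bc     = list(pre = "GrC", post = "BC",
                     geometry = list(half_x = 15, half_y = 15),
                     conv = 600, div = NA_real_, lambda = c(15, 15, 200)),
    sc_pc     = list(pre = "SC", post = "PC",
                     geometry = sc_axon,
                     conv = 6, div = NA_real_,
                     lambda = c(sc_axon$half_x, 150, sc_axon$half_z)),
    bc_pc     = list(pre = "BC", post = "PC",
                     geometry = bc_axon,
                     conv = 6, div = NA_real_,
                     lambda = c(bc_axon$half_x, 150, bc_axon$half_z)),
    aa_pc     = list(pre = "GrC", post = "PC",
                     geometry = list(half_x = 150, half_z = 4),
                     conv = 100, div = NA_real_, lambda = NULL),
    pf_pc     = list(pre = "GrC", post = "PC",
                     geometry = list(half_x = 150),
                     conv = 5000, div = NA_real_, lambda = NULL),
    pc_dcnc   = list(pre = "PC", post = "DCNC",
                     geometry = list(),                 # unregistered volumes
                     conv = 69, div = NA_real_, lambda = NULL),
    glom_dcnc = list(pre = "Glom", post = "DCNC",
                     geometry = list(),
                     conv = 15, div = NA_real_, lambda = NULL)
  )
}

#' Validate a scaffold configuration
#'
#' Checks structural completeness and the physical invariants (positive
#' lengths and densities, `V_r < V_th`, positive synaptic delays, weight sign
#' consistent with the pre-synaptic type).  Called automatically by
#' [scaffold_config()] and [load_config()].
#'
#' @param cfg A `scaffold_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_config <- function(cfg) {
  need <- c("volume", "neurons", "lif", "synapses", "rules", "sim", "aa")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("configuration is missing section(s): ", paste(miss, collapse = ", "))

  v <- cfg$volume
  for (f in names(v))
    if (!is.numeric(v[[f]]) || length(v[[f]]) != 1L || v[[f]] <= 0)
      stop("volume field '", f, "' must be a positive number")

  nt <- cfg$neurons
  if (anyDuplicated(nt$type_code)) stop("neurons: type_code values must be unique")
  if (any(nt$density < 0)) stop("neurons: density must be non-negative")
  if (any(nt$soma_radius <= 0)) stop("neurons: soma_radius must be positive")

  lp <- cfg$lif
  bad <- lp$name[lp$V_r >= lp$V_th]
  if (length(bad)) stop("lif: V_r must be below V_th for ", paste(bad, collapse = ", "))
  for (f in c("C_m", "tau_m", "t_ref", "tau_exc", "tau_inh")) {
    bad <- lp$name[lp[[f]] <= 0]
    if (length(bad)) stop("lif: ", f, " must be positive for ", paste(bad, collapse = ", "))
  }

  sy <- cfg$synapses
  if (any(sy$delay <= 0))
    stop("synapses: delay must be positive for ",
         paste(sy$connection[sy$delay <= 0], collapse = ", "))
  inhibitory_pre <- c("goc", "sc", "bc", "pc")
  pre_tag <- sub("_.*$", "", sy$connection)
  pre_tag[sy$connection %in% c("aa_goc", "aa_pc", "pf_goc", "pf_sc",
                               "pf_bc", "pf_pc")] <- "grc"
  expect_neg <- pre_tag %in% inhibitory_pre
  bad <- sy$connection[(expect_neg & sy$weight > 0) | (!expect_neg & sy$weight < 0)]
  if (length(bad))
    stop("synapses: weight sign inconsistent with pre-synaptic type for ",
         paste(bad, collapse = ", "))

  rl <- cfg$rules
  for (nm in names(rl)) {
    r <- rl[[nm]]
    if (!is.na(r$conv) && r$conv < 0) stop("rules: negative convergence target in ", nm)
    if (!is.na(r$div) && r$div < 0) stop("rules: negative divergence target in ", nm)
  }

  if (cfg$aa$sd <= 0 || cfg$aa$mean <= 0) stop("aa: mean and sd must be positive")
  invisible(cfg)
}

#' @export
print.scaffold_config <- function(x, ...) {
  v <- x$volume
  cat("Cerebellar scaffold configuration\n")
  cat(sprintf("  cortex: %g x %g um^2 base, %g um height (gr %g / pc %g / mol %g)\n",
              v$base_x, v$base_z,
              v$granular_height + v$pc_layer_height + v$molecular_height,
              v$granular_height, v$pc_layer_height, v$molecular_height))
  cat(sprintf("  DCN:    %g x %g x %g um^3\n", v$dcn_base_x, v$dcn_base_z, v$dcn_height))
  cat(sprintf("  neuron types: %d; connection types: %d\n",
              nrow(x$neurons), nrow(x$synapses)))
  ec <- expected_counts(x)
  cat(sprintf("  expected cells: %d (%s)\n", sum(ec),
              paste(sprintf("%s %d", names(ec), ec), collapse = ", ")))
  invisible(x)
}

#' Vertical extent of each layer
#'
#' @param cfg A `scaffold_config`.
#' @return Named list of `c(y_lo, y_hi)` for the granular, Purkinje-cell and
#'   molecular layers, the two molecular half-layers, and the DCN block
#'   (placed logically below the cortical slab, negative y).
#' @export
layer_bounds <- function(cfg) {
  v <- cfg$volume
  g <- v$granular_height; p <- v$pc_layer_height; m <- v$molecular_height
  list(
    granular        = c(0, g),
    pc              = c(g, g + p),
    molecular       = c(g + p, g + p + m),
    molecular_lower = c(g + p, g + p + m / 2),
    molecular_upper = c(g + p + m / 2, g + p + m),
    dcn             = c(-v$dcn_height, 0)
  )
}

#' Expected per-type cell counts
#'
#' Target counts implied by the configured densities: volumetric density times
#' layer volume for all types except Purkinje cells, whose planar density
#' multiplies the base area, and DCN cells, which use the DCN block volume.
#'
#' @param cfg A `scaffold_config`.
#' @return Named integer vector of target counts, one per neuron type.
#' @examples
#' expected_counts(scaffold_config())["DCNC"]  # 12
#' @export
expected_counts <- function(cfg) {
  v <- cfg$volume
  lb <- layer_bounds(cfg)
  base_area <- v$base_x * v$base_z
  out <- integer(nrow(cfg$neurons))
  names(out) <- cfg$neurons$name
  for (i in seq_len(nrow(cfg$neurons))) {
    row <- cfg$neurons[i, ]
    out[i] <- if (row$layer == "pc") {
      round(row$density * base_area)
    } else if (row$layer == "dcn") {
      round(row$density * v$dcn_base_x * v$dcn_base_z * v$dcn_height)
    } else {
      h <- diff(lb[[row$layer]])
      round(row$density * base_area * h)
    }
  }
  out
}

#' Write a configuration to a YAML file
#'
#' @param cfg A `scaffold_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ser <- list(
    volume   = cfg$volume,
    neurons  = as.list(cfg$neurons),
    lif      = as.list(cfg$lif),
    synapses = as.list(cfg$synapses),
    rules    = lapply(cfg$rules, function(r) {
      r$lambda <- if (is.null(r$lambda)) "flat" else r$lambda
      r
    }),
    sim      = cfg$sim,
    aa       = cfg$aa,
    orthogonal_plexus = isTRUE(cfg$orthogonal_plexus)
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read and validate a configuration from a YAML file
#'
#' @param path Path to a YAML file written by [save_config()].
#' @return A validated `scaffold_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ser <- yaml::read_yaml(path)
  need <- c("volume", "neurons", "lif", "synapses", "rules", "sim", "aa")
  miss <- setdiff(need, names(ser))
  if (length(miss))
    stop("configuration file is missing section(s): ", paste(miss, collapse = ", "))
  cfg <- list(
    volume   = ser$volume,
    neurons  = as.data.frame(ser$neurons, stringsAsFactors = FALSE),
    lif      = as.data.frame(ser$lif, stringsAsFactors = FALSE),
    synapses = as.data.frame(ser$synapses, stringsAsFactors = FALSE),
    rules    = lapply(ser$rules, function(r) {
      r$conv <- if (is.null(r$conv)) NA_real_ else as.numeric(r$conv)
      r$div  <- if (is.null(r$div)) NA_real_ else as.numeric(r$div)
      if (identical(r$lambda, "flat")) r["lambda"] <- list(NULL)
      else r$lambda <- as.numeric(r$lambda)
      r
    }),
    sim      = ser$sim,
    aa       = ser$aa,
    orthogonal_plexus = isTRUE(ser$orthogonal_plexus)
  )
  class(cfg) <- "scaffold_config"
  validate_config(cfg)
  cfg
}
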