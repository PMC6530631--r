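## The simulation experiments: default mossy-fiber burst, switch-off
## variants, center-surround pair, oscillation regime, orthogonal-plexus
## molecular-layer variant.

new_protocol <- function(name, T_sim, background_rate, burst = NULL,
                         switch_off = character(), weight_overrides = NULL) {
  if (!is.null(burst))
    stopifnot(burst$onset >= 0, burst$onset + burst$duration <= T_sim)
  structure(list(name = name, T_sim = T_sim,
                 background_rate = background_rate, burst = burst,
                 switch_off = switch_off,
                 weight_overrides = weight_overrides),
            class = "scaffold_protocol")
}

#' @export
print.scaffold_protocol <- function(x, ...) {
  cat("Protocol '", x$name, "': ", x$T_sim, " ms, background ",
      x$background_rate, " Hz", sep = "")
  if (!is.null(x$burst))
    cat(sprintf(", burst %g Hz x %g ms at t=%g", x$burst$rate,
                x$burst$duration, x$burst$onset))
  cat("\n")
  invisible(x)
}

#' Default mossy-fiber burst protocol
#'
#' One second of simulation: 1 Hz Poisson background on all glomeruli with a
#' 150 Hz, 50 ms burst starting at 300 ms in a 140 um-radius stimulated
#' volume centered on the cortical base (300 ms pre-stimulus, 50 ms stimulus,
#' 650 ms post-stimulus).
#'
#' @param cfg A `scaffold_config` (for the volume center).
#' @return A `scaffold_protocol`.
#' @export
default_protocol <- function(cfg = scaffold_config()) {
  v <- cfg$volume
  new_protocol("default", T_sim = 1000, background_rate = 1,
               burst = list(onset = 300, duration = 50, rate = 150,
                            center = c(v$base_x / 2,
                                       v$granular_height / 2,
                                       v$base_z / 2),
                            radius = 140))
}

#' Center-surround protocol pair
#'
#' Control and inhibition-off protocols for the center-surround analysis: the
#' burst (150 Hz, 50 ms) is restricted to the 40 glomeruli nearest the
#' stimulation center; the second protocol is identical but is meant to be
#' simulated with the GoC-GrC inhibition switched off.  Granule-cell rates
#' are then compared in the windows 0-20 ms (T1) and 20-40 ms (T2) after
#' burst onset.
#'
#' @param cfg A `scaffold_config`.
#' @param n_gloms Number of stimulated glomeruli (default 40).
#' @return List with elements `control` and `inhibition_off`.
#' @export
cs_protocol <- function(cfg = scaffold_config(), n_gloms = 40) {
  v <- cfg$volume
  base <- new_protocol("cs_control", T_sim = 1000, background_rate = 1,
                       burst = list(onset = 300, duration = 50, rate = 150,
                                    center = c(v$base_x / 2,
                                               v$granular_height / 2,
                                               v$base_z / 2),
                                    radius = NA, n_gloms = n_gloms))
  inoff <- base
  inoff$name <- "cs_inhibition_off"
  inoff$switch_off <- "goc_grc"
  list(control = base, inhibition_off = inoff)
}

#' Oscillation protocol
#'
#' Five seconds of sustained noisy background at 5 Hz on all glomeruli, no
#' burst, with the parallel-fiber to Golgi-cell weight raised to 30.4 nS:
#' the regime in which the granular layer develops coherent low-frequency
#' oscillations.
#'
#' @return A `scaffold_protocol`.
#' @export
oscillation_protocol <- function() {
  new_protocol("oscillation", T_sim = 5000, background_rate = 5,
               weight_overrides = c(pf_goc = 30.4))
}

#' Orthogonal-plexus experiment
#'
#' Rebuilds connectivity with the stellate- and basket-cell axonal plexus
#' orientations swapped and concentrates the burst in a 30 um-radius volume.
#'
#' @param cfg Base `scaffold_config` (its scale is kept).
#' @return List with `config` (the orthogonal-plexus configuration) and
#'   `protocol`.
#' @export
orthogonal_plexus_protocol <- function(cfg = scaffold_config()) {
  v <- cfg$volume
  cfg2 <- scaffold_config(scale = v$base_x / 400, orthogonal_plexus = TRUE)
  proto <- new_protocol("orthogonal", T_sim = 1000, background_rate = 1,
                        burst = list(onset = 300, duration = 50, rate = 150,
                                     center = c(v$base_x / 2,
                                                v$granular_height / 2,
                                                v$base_z / 2),
                                     radius = 30))
  list(config = cfg2, protocol = proto)
}

#' Run one protocol end to end
#'
#' Convenience wrapper: assembles the network with the protocol's weight
#' overrides and switch-offs, builds the stimulus, and simulates.
#'
#' @param placement A `scaffold_placement`.
#' @param connectome A `scaffold_connectome`.
#' @param protocol A `scaffold_protocol`.
#' @param seed Integer seed (stimulus randomness).
#' @param switch_off Additional connection names to silence.
#' @return A `scaffold_spikes` object.
#' @export
run_protocol <- function(placement, connectome, protocol, seed = 1L,
                         switch_off = character()) {
  net <- assemble_network(placement, connectome,
                          weight_overrides = protocol$weight_overrides,
                          switch_off = union(protocol$switch_off, switch_off))
  stim <- make_stimulus(placement, protocol, seed = seed)
  sp <- simulate_network(net, stim, protocol$T_sim)
  attr(sp, "protocol") <- protocol
  attr(sp, "stimulated_gloms") <- stimulus_glom_ids(placement, protocol)
  sp
}

#' Glomeruli stimulated by a protocol
#'
#' Pure function of the placement and the protocol's burst definition.
#'
#' @param placement A `scaffold_placement`.
#' @param protocol A `scaffold_protocol`.
#' @return Integer vector of stimulated glom cell ids (empty if no burst).
#' @export
stimulus_glom_ids <- function(placement, protocol) {
  if (is.null(protocol$burst)) return(integer(0))
  gloms <- type_positions(placement, "Glom")
  gloms$cell_id[stimulated_gloms(gloms, protocol$burst)]
}
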