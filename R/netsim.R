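## Conductance-based exponential-synapse LIF network simulation at fixed
## 0.1 ms resolution.  Glomeruli are parrot relays reproducing the imposed
## mossy-fiber stimulus.

#' Assemble a simulatable network
#'
#' Attaches one LIF unit (per-type parameters) to every non-glomerulus cell,
#' marks glomeruli as parrot relays, and instantiates one synapse per
#' connectome edge with the connection type's weight and delay.  Negative
#' weights are routed to the target's inhibitory conductance channel (the
#' increment is the absolute value).
#'
#' @param placement A `scaffold_placement`.
#' @param connectome A `scaffold_connectome` built from it.
#' @param weight_overrides Named numeric vector, connection name -> weight
#'   (nS), replacing the table value (e.g. `c(pf_goc = 30.4)`).
#' @param switch_off Character vector of connection names whose synapses are
#'   set to zero weight (structure retained); see [apply_switch_off()].
#' @return A `scaffold_network`: list with `cells`, `lif_index`, `syn`
#'   (data.table `pre`, `post`, `connection`, `weight`, `base_weight`,
#'   `delay`), and `config`.
#' @export
assemble_network <- function(placement, connectome,
                             weight_overrides = NULL,
                             switch_off = character()) {
  cfg <- connectome$config
  cells <- placement$cells
  if (!all(cells$cell_id == seq_len(nrow(cells))))
    stop("placement cell_ids must be contiguous 1..N")

  syn_tab <- cfg$synapses
  if (length(weight_overrides)) {
    bad <- setdiff(names(weight_overrides), syn_tab$connection)
    if (length(bad)) stop("unknown connection in weight_overrides: ",
                          paste(bad, collapse = ", "))
    syn_tab$weight[match(names(weight_overrides), syn_tab$connection)] <-
      unname(weight_overrides)
  }

  parts <- vector("list", nrow(syn_tab))
  for (k in seq_len(nrow(syn_tab))) {
    nm <- syn_tab$connection[k]
    e <- connectome$edges[[nm]]
    if (is.null(e)) stop("connectome is missing connection type ", nm)
    if (!nrow(e)) next
    bad <- c(setdiff(e$pre_id, cells$cell_id), setdiff(e$post_id, cells$cell_id))
    if (length(bad))
      stop("edges of ", nm, " reference unknown cell ids: ",
           paste(head(bad, 5), collapse = ", "))
    parts[[k]] <- data.table::data.table(
      pre = e$pre_id, post = e$post_id, connection = nm,
      weight = syn_tab$weight[k], delay = syn_tab$delay[k])
  }
  syn <- data.table::rbindlist(parts)
  if (!nrow(syn))
    syn <- data.table::data.table(pre = integer(), post = integer(),
                                  connection = character(),
                                  weight = numeric(), delay = numeric())
  syn$base_weight <- syn$weight
  data.table::setorder(syn, pre, post)

  net <- list(
    cells = cells,
    lif_index = match(cells$type, cfg$lif$name),  # NA for parrot gloms
    syn = syn,
    config = cfg)
  class(net) <- "scaffold_network"
  if (length(switch_off)) net <- apply_switch_off(net, switch_off)
  net
}

#' @export
print.scaffold_network <- function(x, ...) {
  cat("Scaffold network:", nrow(x$cells), "neurons,", nrow(x$syn),
      "synapses\n")
  off <- unique(x$syn$connection[x$syn$weight == 0 & x$syn$base_weight != 0])
  if (length(off)) cat("  switched off:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

#' Switch off (or restore) connection types
#'
#' Sets the weight of every synapse of the named connection types to zero
#' while keeping the edges, so the operation is reversible and composable.
#'
#' @param network A `scaffold_network`.
#' @param names Connection names to silence; must exist in the synapse table.
#' @param restore If `TRUE`, restore the named connections to their base
#'   weights instead.
#' @return The modified network.
#' @export
apply_switch_off <- function(network, names, restore = FALSE) {
  bad <- setdiff(names, network$config$synapses$connection)
  if (length(bad)) stop("unknown connection name(s): ",
                        paste(bad, collapse = ", "))
  sel <- network$syn$connection %in% names
  network$syn$weight[sel] <- if (restore) network$syn$base_weight[sel] else 0
  network
}

#' Mossy-fiber stimulus for the glomeruli
#'
#' Background activity is an independent Poisson process on every glomerulus.
#' Gloms inside the stimulated volume additionally receive a regular burst
#' train: spikes at `onset + k/rate` for `k = 0 .. floor(duration * rate) - 1`,
#' so a 150 Hz, 50 ms burst delivers 7 spikes starting at onset (~140 Hz
#' measured over the window).  The stimulated
#' volume is a vertical cylinder of the given radius spanning the granular
#' layer (mossy-fiber bundles run through the full layer depth).  All times
#' are snapped to the simulation grid.
#'
#' @param placement A `scaffold_placement`.
#' @param protocol A `scaffold_protocol` from e.g. [default_protocol()].
#' @param seed Integer seed for the Poisson background.
#' @return List with `times` (list of spike-time vectors, one per glom, in
#'   cell-id order), `glom_ids`, and `stimulated` (logical per glom).
#' @export
make_stimulus <- function(placement, protocol, seed = 1L) {
  cfg <- placement$config
  dt <- cfg$sim$dt
  gloms <- type_positions(placement, "Glom")
  set.seed(seed)
  T_sim <- protocol$T_sim
  rate <- protocol$background_rate

  n_bg <- if (rate > 0)
    stats::rpois(nrow(gloms), rate * T_sim / 1000) else integer(nrow(gloms))
  times <- lapply(n_bg, function(k) if (k > 0) runif(k, 0, T_sim) else numeric(0))

  stimulated <- rep(FALSE, nrow(gloms))
  if (!is.null(protocol$burst)) {
    b <- protocol$burst
    stimulated <- stimulated_gloms(gloms, b)
    period <- 1000 / b$rate
    burst_t <- b$onset + period * (seq_len(floor(b$duration / period)) - 1)
    times[stimulated] <- lapply(times[stimulated],
                                function(t) c(t, burst_t))
  }
  times <- lapply(times, function(t) {
    t <- sort(unique(round(t / dt) * dt))
    t[t >= 0 & t < T_sim]
  })
  list(times = times, glom_ids = gloms$cell_id, stimulated = stimulated)
}

## Gloms inside the stimulated volume.  If `burst$n_gloms` is given, the n
## gloms nearest to the center (transverse distance) are selected instead of
## a fixed radius.
stimulated_gloms <- function(gloms, burst) {
  d2 <- (gloms$x - burst$center[1])^2 + (gloms$z - burst$center[3])^2
  if (!is.null(burst$n_gloms)) {
    sel <- rep(FALSE, nrow(gloms))
    sel[order(d2)[seq_len(min(burst$n_gloms, nrow(gloms)))]] <- TRUE
    sel
  } else {
    d2 <= burst$radius^2
  }
}

#' Simulate the network
#'
#' Runs the LIF dynamics for the whole network at the configured resolution.
#' Parrot glomeruli emit the stimulus verbatim and propagate it through their
#' efferent synapses with the table delays.
#'
#' @param network A `scaffold_network`.
#' @param stimulus Output of [make_stimulus()].
#' @param T_sim Simulation length (ms).
#' @return A `scaffold_spikes`: data.table `id`, `t` (ms, sorted by `t`),
#'   with the simulated duration and the cell table as attributes.
#' @export
simulate_network <- function(network, stimulus, T_sim) {
  cfg <- network$config
  dt <- cfg$sim$dt
  n <- nrow(network$cells)
  lifi <- network$lif_index
  type_idx <- ifelse(is.na(lifi), -1L, lifi - 1L)

  syn <- network$syn
  counts <- tabulate(syn$pre, nbins = n)
  syn_ptr <- c(0L, cumsum(counts))
  delay_steps <- pmax(1L, as.integer(round(syn$delay / dt)))

  stim_counts <- integer(n)
  stim_counts[stimulus$glom_ids] <- lengths(stimulus$times)
  stim_ptr <- c(0L, cumsum(stim_counts))
  stim_time <- numeric(sum(stim_counts))
  if (sum(stim_counts) > 0) {
    ord <- order(rep(stimulus$glom_ids, lengths(stimulus$times)))
    stim_time <- unlist(stimulus$times, use.names = FALSE)[ord]
  }
  stim_step <- as.integer(round(stim_time / dt))

  lp <- cfg$lif
  res <- sim_engine_cpp(
    as.integer(type_idx),
    lp$C_m, lp$tau_m, lp$E_L, lp$t_ref, lp$I_e, lp$V_r, lp$V_th,
    lp$tau_exc, lp$tau_inh,
    as.integer(syn_ptr), as.integer(syn$post - 1L), syn$weight,
    delay_steps,
    as.integer(stim_ptr), stim_step, stim_time,
    dt, cfg$sim$E_exc, cfg$sim$E_inh, as.integer(round(T_sim / dt)))

  spikes <- data.table::data.table(id = res$id + 1L, t = res$t)
  data.table::setorder(spikes, t, id)
  structure(spikes, class = c("scaffold_spikes", class(spikes)),
            T_sim = T_sim, cells = network$cells)
}

#' Intrinsic firing rate of a LIF type
#'
#' Closed-form rate of an isolated LIF neuron driven only by its constant
#' input current: with `R = tau_m / C_m`, the rate is 0 if
#' `E_L + I_e R <= V_th`, otherwise
#' `1000 / (t_ref + tau_m * log((E_L + I_e R - V_r) / (E_L + I_e R - V_th)))`.
#'
#' @param params One row of the LIF table (list or data.frame row).
#' @return Rate in Hz.
#' @examples
#' cfg <- scaffold_config()
#' intrinsic_rate(subset(cfg$lif, name == "GrC"))   # 0: no autorhythmicity
#' intrinsic_rate(subset(cfg$lif, name == "DCNC"))  # ~25.8 Hz
#' @export
intrinsic_rate <- function(params) {
  with(as.list(params), {
    v_inf <- E_L + I_e * tau_m / C_m
    if (v_inf <= V_th) return(0)
    1000 / (t_ref + tau_m * log((v_inf - V_r) / (v_inf - V_th)))
  })
}
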