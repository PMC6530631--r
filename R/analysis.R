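## Network data analysis: rates, PSTH, excited/inhibited classification,
## Purkinje burst-pause detection, center-surround EI/CS maps, correlograms
## and the coherence index.

spike_table <- function(spikes) {
  if (inherits(spikes, "scaffold_spikes") || is.data.frame(spikes))
    return(as.data.frame(spikes)[, c("id", "t")])
  stop("spikes must be a scaffold_spikes object or a data.frame with id, t")
}

#' Peri-stimulus time histogram
#'
#' Spike counts per time bin across a set of neurons, with left-closed bins
#' (`[k b, (k+1) b)`).
#'
#' @param spikes A `scaffold_spikes` or data.frame with `id`, `t`.
#' @param ids Neuron ids to include (default: all).
#' @param bin Bin width in ms (default 3).
#' @param T_sim Total duration (ms); defaults to the spikes attribute.
#' @return data.frame with `t` (bin left edge, ms) and `count`.
#' @export
psth <- function(spikes, ids = NULL, bin = 3, T_sim = attr(spikes, "T_sim")) {
  stopifnot(bin > 0)
  sp <- spike_table(spikes)
  if (!is.null(ids)) sp <- sp[sp$id %in% ids, ]
  if (is.null(T_sim)) T_sim <- if (nrow(sp)) max(sp$t) else bin
  n_bins <- ceiling(T_sim / bin)
  counts <- tabulate(pmin(floor(sp$t / bin), n_bins - 1) + 1L, n_bins)
  data.frame(t = (seq_len(n_bins) - 1) * bin, count = counts)
}

#' Per-cell and per-population firing rates in protocol windows
#'
#' Mean firing rates in three windows: baseline (the pre-stimulus interval),
#' during (the stimulus), and after (the steady-state tail of the run).
#'
#' @param spikes A `scaffold_spikes` (or data.frame `id`, `t`).
#' @param cells Cell table (`cell_id`, `type`); defaults to the spikes
#'   attribute.
#' @param windows List of `c(start, end)` ms with names `before`, `during`,
#'   `after`; defaults to the reference burst protocol (0-300, 300-350,
#'   700-1000).
#' @return A `scaffold_rates`: list with `cell_rates` (per cell, Hz per
#'   window) and `population` (mean +/- sd per type per window).
#' @export
mean_rates <- function(spikes, cells = attr(spikes, "cells"),
                       windows = list(before = c(0, 300),
                                      during = c(300, 350),
                                      after = c(700, 1000))) {
  sp <- spike_table(spikes)
  stopifnot(!is.null(cells))
  rates <- data.frame(cell_id = cells$cell_id, type = cells$type)
  for (w in names(windows)) {
    win <- windows[[w]]
    stopifnot(length(win) == 2, win[2] > win[1])
    n <- tabulate(match(sp$id[sp$t >= win[1] & sp$t < win[2]],
                        cells$cell_id), nrow(cells))
    rates[[w]] <- 1000 * n / (win[2] - win[1])
  }
  pop <- do.call(rbind, lapply(split(rates, rates$type), function(d) {
    out <- data.frame(type = d$type[1], n_cells = nrow(d))
    for (w in names(windows)) {
      out[[paste0(w, "_mean")]] <- mean(d[[w]])
      out[[paste0(w, "_sd")]] <- sd(d[[w]])
    }
    out
  }))
  rownames(pop) <- NULL
  structure(list(cell_rates = rates, population = pop, windows = windows),
            class = "scaffold_rates")
}

#' @export
print.scaffold_rates <- function(x, ...) {
  print(x$population, digits = 3)
  invisible(x)
}

#' Classify stimulus responses as excited, inhibited or unchanged
#'
#' A cell is excited if its during-stimulus rate is at least double the
#' baseline rate (granule cells must additionally fire more than 1 spike
#' during the stimulus, excluding background-driven singletons), inhibited if
#' the during rate is at most half the baseline.  Cells with a silent
#' baseline are excited if they meet the spike requirement (> 1 spike for
#' GrCs, >= 1 otherwise) and are never inhibited.
#'
#' @param spikes A `scaffold_spikes` (or data.frame `id`, `t`).
#' @param cells Cell table; defaults to the spikes attribute.
#' @param windows List with `before` and `during` windows (ms).
#' @return data.frame `cell_id`, `type`, `before`, `during` (Hz),
#'   `response` (factor excited/inhibited/unchanged).
#' @export
classify_response <- function(spikes, cells = attr(spikes, "cells"),
                              windows = list(before = c(0, 300),
                                             during = c(300, 350))) {
  r <- mean_rates(spikes, cells, windows[c("before", "during")])$cell_rates
  dur_len <- diff(windows$during)
  n_during <- r$during * dur_len / 1000
  min_spikes <- ifelse(r$type == "GrC", 2L, 1L)
  excited <- ifelse(r$before > 0,
                    r$during >= 2 * r$before & n_during >= min_spikes,
                    n_during >= min_spikes)
  inhibited <- r$before > 0 & r$during <= r$before / 2 & !excited
  r$response <- factor(ifelse(excited, "excited",
                              ifelse(inhibited, "inhibited", "unchanged")),
                       levels = c("excited", "inhibited", "unchanged"))
  r
}

#' Purkinje burst-pause detection
#'
#' A PC shows a pause when its first inter-spike interval after stimulus end
#' exceeds the mean pre-stimulus ISI by more than two pre-stimulus ISI
#' standard deviations (within-cell comparison; the mean offset keeps the
#' rule sensible for near-regular trains where the sd vanishes).  A burst is
#' an excited classification over the stimulus window; cells showing both
#' get the combined label.
#'
#' @param spikes A `scaffold_spikes` (or data.frame `id`, `t`).
#' @param pc_ids Purkinje cell ids.
#' @param stim Window `c(start, end)` of the stimulus (ms).
#' @param responses Optional precomputed [classify_response()] output.
#' @param cells Cell table; defaults to the spikes attribute.
#' @return data.frame `cell_id`, `label` in
#'   `{burst, pause, burst_and_pause, none, undetermined}`.
#' @export
detect_burst_pause <- function(spikes, pc_ids, stim = c(300, 350),
                               responses = NULL,
                               cells = attr(spikes, "cells")) {
  sp <- spike_table(spikes)
  if (is.null(responses))
    responses <- classify_response(spikes, cells,
                                   windows = list(before = c(0, stim[1]),
                                                  during = stim))
  labs <- character(length(pc_ids))
  for (k in seq_along(pc_ids)) {
    tt <- sort(sp$t[sp$id == pc_ids[k]])
    pre_isi <- diff(tt[tt < stim[1]])
    post <- tt[tt >= stim[2]]
    burst <- responses$response[responses$cell_id == pc_ids[k]] == "excited"
    if (length(pre_isi) < 3) { labs[k] <- "undetermined"; next }
    last_spk <- max(tt[tt < stim[2]])
    first_post_isi <- if (length(post)) post[1] - last_spk else
      max(sp$t, stim[2]) - last_spk  # silent tail counts as a long interval
    pause <- first_post_isi > mean(pre_isi) + 2 * sd(pre_isi)
    labs[k] <- if (burst && pause) "burst_and_pause"
               else if (pause) "pause"
               else if (burst) "burst" else "none"
  }
  data.frame(cell_id = pc_ids, label = labs)
}

#' Excitatory-inhibitory balance and center-surround maps
#'
#' Pixelwise over a 2D grid of the granular layer:
#' `EI = FR_con(T2) - FR_inoff(T2)` and `CS = FR_con(T1) - EI`, with CS then
#' normalized by its maximum absolute value to `[-1, 1]`.  The center is the
#' set of pixels with `CS > 0.5`, the surround those with `CS < -0.5`;
#' relative areas are pixel counts over the total.
#'
#' @param fr_con_t1,fr_con_t2,fr_inoff_t2 Numeric vectors of per-pixel
#'   granule-cell firing rates (Hz) on a common grid: control T1, control T2,
#'   and inhibition-off T2.
#' @return A `scaffold_cs_map`: list with `EI`, `CS_raw`, `CS` (normalized),
#'   `center`, `surround` (logical masks), `center_area`, `surround_area`
#'   (relative), and `normalized` (FALSE when CS was all zero).
#' @export
compute_EI_CS <- function(fr_con_t1, fr_con_t2, fr_inoff_t2) {
  stopifnot(length(fr_con_t1) == length(fr_con_t2),
            length(fr_con_t2) == length(fr_inoff_t2))
  EI <- fr_con_t2 - fr_inoff_t2
  CS_raw <- fr_con_t1 - EI
  m <- max(abs(CS_raw))
  normalized <- m > 0
  CS <- if (normalized) CS_raw / m else CS_raw
  center <- CS > 0.5
  surround <- CS < -0.5
  structure(list(EI = EI, CS_raw = CS_raw, CS = CS,
                 center = center, surround = surround,
                 center_area = mean(center), surround_area = mean(surround),
                 normalized = normalized),
            class = "scaffold_cs_map")
}

#' @export
print.scaffold_cs_map <- function(x, ...) {
  cat(sprintf(
    "Center-surround map: %d pixels; center area %.3f, surround area %.3f%s\n",
    length(x$CS), x$center_area, x$surround_area,
    if (!x$normalized) " (all-zero CS, not normalized)" else ""))
  invisible(x)
}

#' Per-pixel granule-cell rates on a spatial grid
#'
#' Bins GrCs into square (x, z) pixels over the granular layer by soma
#' position and returns the mean firing rate per pixel in a time window.
#'
#' @param spikes A `scaffold_spikes`.
#' @param placement The `scaffold_placement`.
#' @param window `c(start, end)` ms.
#' @param pixel Pixel side (um, default 10).
#' @return List with `rate` (matrix, x rows by z cols, Hz; NA for empty
#'   pixels) and the bin edges.
#' @export
grc_rate_map <- function(spikes, placement, window, pixel = 10) {
  sp <- spike_table(spikes)
  v <- placement$config$volume
  g <- type_positions(placement, "GrC")
  n_sp <- tabulate(match(sp$id[sp$t >= window[1] & sp$t < window[2]],
                         g$cell_id), nrow(g))
  rate <- 1000 * n_sp / (window[2] - window[1])
  ix <- pmin(floor(g$x / pixel) + 1L, ceiling(v$base_x / pixel))
  iz <- pmin(floor(g$z / pixel) + 1L, ceiling(v$base_z / pixel))
  nx <- ceiling(v$base_x / pixel); nz <- ceiling(v$base_z / pixel)
  sum_map <- matrix(0, nx, nz); cnt <- matrix(0L, nx, nz)
  for (k in seq_along(rate)) {
    sum_map[ix[k], iz[k]] <- sum_map[ix[k], iz[k]] + rate[k]
    cnt[ix[k], iz[k]] <- cnt[ix[k], iz[k]] + 1L
  }
  out <- sum_map / cnt
  out[cnt == 0] <- NA
  list(rate = out,
       x_edges = (0:nx) * pixel, z_edges = (0:nz) * pixel)
}

#' Correlogram and coherence of binned spike trains
#'
#' Bins the two spike trains on a common grid, mean-subtracts, and computes
#' the normalized cross-correlation over lags up to `max_lag`.  The
#' coherence index is `C = sum(|A_n|) / len(A)` over the correlation array,
#' and the dominant frequency is the reciprocal of the lag of the first
#' positive-lag local maximum.
#'
#' @param t_a,t_b Spike-time vectors (ms); pass the same train twice for an
#'   autocorrelogram.
#' @param bin Bin width (ms, default 10).
#' @param max_lag Maximum lag (ms, default 2000).
#' @param T_sim Duration (ms) for binning; default covers the data.
#' @return A `scaffold_correlogram`: `lag` (ms), `cor`, `coherence`,
#'   `dominant_freq` (Hz, NA if no positive-lag peak).
#' @export
correlogram <- function(t_a, t_b, bin = 10, max_lag = 2000, T_sim = NULL) {
  if (!length(t_a) || !length(t_b)) stop("empty spike train")
  if (is.null(T_sim)) T_sim <- max(t_a, t_b) + bin
  n_bins <- ceiling(T_sim / bin)
  a <- tabulate(pmin(floor(t_a / bin), n_bins - 1) + 1L, n_bins)
  b <- tabulate(pmin(floor(t_b / bin), n_bins - 1) + 1L, n_bins)
  a <- a - mean(a); b <- b - mean(b)
  denom <- sqrt(sum(a^2) * sum(b^2))
  if (denom == 0) stop("constant binned train: correlation undefined")
  k_max <- min(n_bins - 1, floor(max_lag / bin))
  lags <- (-k_max):k_max
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[seq_len(n_bins - k)] * b[seq_len(n_bins - k) + k])
    else sum(a[seq_len(n_bins + k) - k] * b[seq_len(n_bins + k)])
  }, numeric(1)) / denom
  pos <- which(lags > 0)
  i <- pos[-c(1, length(pos))]
  peaks <- i[cc[i] > cc[i - 1] & cc[i] >= cc[i + 1] & cc[i] > 0]
  dom <- if (length(peaks)) 1000 / (lags[peaks[1]] * bin) else NA_real_
  structure(list(lag = lags * bin, cor = cc,
                 coherence = coherence_index(cc),
                 dominant_freq = dom),
            class = "scaffold_correlogram")
}

#' Coherence index of a correlation array
#'
#' `C = sum(|A_n|) / len(A)`, the mean absolute correlation.
#'
#' @param A Numeric array of correlation values.
#' @return Non-negative scalar.
#' @export
coherence_index <- function(A) {
  if (!length(A)) return(0)
  sum(abs(A)) / length(A)
}

#' @export
print.scaffold_correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: coherence %.4f, dominant frequency %s Hz\n",
              x$coherence,
              if (is.na(x$dominant_freq)) "NA" else
                sprintf("%.2f", x$dominant_freq)))
  invisible(x)
}

#' @export
plot.scaffold_correlogram <- function(x, ...) {
  plot(x$lag, x$cor, type = "l", xlab = "lag (ms)", ylab = "correlation", ...)
  invisible(x)
}

#' Golgi cells with overlapping parallel-fiber inputs, and their granule cells
#'
#' The subset used for the oscillation analysis: GoCs whose parallel-fiber
#' afferent sets share at least one granule cell, together with those shared
#' granule cells.
#'
#' @param connectome A `scaffold_connectome`.
#' @return List with `goc_ids` and `grc_ids`.
#' @export
oscillation_subset <- function(connectome) {
  e <- connectome$edges$pf_goc
  if (is.null(e) || !nrow(e)) return(list(goc_ids = integer(), grc_ids = integer()))
  dup <- e$pre_id[duplicated(e$pre_id) | duplicated(e$pre_id, fromLast = TRUE)]
  shared <- unique(dup)
  sel <- e[e$pre_id %in% shared, ]
  list(goc_ids = sort(unique(sel$post_id)), grc_ids = sort(unique(sel$pre_id)))
}
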