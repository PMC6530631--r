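mk_spikes <- function(ids, times, T_sim = 1000,
                      cells = NULL) {
  dt <- data.table::data.table(id = ids, t = times)
  data.table::setorder(dt, t, id)
  structure(dt, class = c("scaffold_spikes", class(dt)),
            T_sim = T_sim, cells = cells)
}

test_that("PSTH bins are left-closed and counts are conserved", {
  sp <- mk_spikes(c(1, 1, 2), c(0, 3.0, 7.2), T_sim = 12)
  h <- psth(sp, bin = 3)
  expect_equal(h$t, c(0, 3, 6, 9))
  expect_equal(h$count, c(1, 1, 1, 0))      # t = 3.0 falls in [3, 6)
  expect_equal(sum(h$count), 3)
  empty <- psth(mk_spikes(integer(0), numeric(0), T_sim = 9), bin = 3)
  expect_equal(empty$count, c(0, 0, 0))
  expect_error(psth(sp, bin = 0), "bin > 0")
})

test_that("window rates normalize by duration per cell and population", {
  cells <- data.frame(cell_id = 1:3, type = c("GrC", "GrC", "PC"))
  sp <- mk_spikes(c(1, 1, 1, 2, 3, 3),
                  c(10, 200, 320, 340, 100, 800), cells = cells)
  r <- mean_rates(sp, cells,
                  windows = list(before = c(0, 300), during = c(300, 350),
                                 after = c(700, 1000)))
  cr <- r$cell_rates
  expect_equal(cr$before, c(2 / 0.3, 0, 1 / 0.3))
  expect_equal(cr$during, c(20, 20, 0))
  expect_equal(cr$after, c(0, 0, 1 / 0.3))
  pop <- r$population
  expect_equal(pop$n_cells[pop$type == "GrC"], 2)
  expect_equal(pop$during_mean[pop$type == "GrC"], 20)
})

test_that("excited/inhibited classification follows the doubling rule", {
  cells <- data.frame(cell_id = 1:5,
                      type = c("PC", "PC", "GrC", "GrC", "PC"))
  trains <- list(
    c(seq(0, 299, length.out = 3), 310, 320),        # 10 -> 40 Hz: excited
    seq(0, 299, length.out = 6),                     # 20 -> 0 Hz: inhibited
    310,                                             # GrC, single during spike
    c(315, 335),                                     # GrC, two during spikes
    c(seq(10, 290, length.out = 6), 322))            # rate kept: unchanged
  ids <- rep(seq_along(trains), lengths(trains))
  sp <- mk_spikes(ids, unlist(trains), cells = cells)
  out <- classify_response(sp, cells,
                           windows = list(before = c(0, 300),
                                          during = c(300, 350)))
  expect_equal(as.character(out$response),
               c("excited", "inhibited", "unchanged", "excited", "unchanged"))
})

test_that("classification is invariant to rescaling both windows", {
  cells <- data.frame(cell_id = 1, type = "PC")
  sp <- mk_spikes(rep(1, 8), c(seq(0, 290, length.out = 6), 305, 315),
                  cells = cells)
  a <- classify_response(sp, cells,
                         windows = list(before = c(0, 300),
                                        during = c(300, 350)))
  ## same spike trains viewed through windows scaled in duration by 1/2
  b <- classify_response(sp, cells,
                         windows = list(before = c(150, 300),
                                        during = c(300, 325)))
  ## rates double but the ratio rule is scale-free
  expect_equal(as.character(a$response), "excited")
  expect_equal(as.character(b$response), "excited")
})

test_that("burst-pause detection compares the first post-stimulus interval", {
  cells <- data.frame(cell_id = 1:3, type = rep("PC", 3))
  ## regular 50 ms pre-train (sd = 0); cell 1 pauses (post ISI 3x mean),
  ## cell 2 resumes on schedule, cell 3 has too few pre-ISIs
  pre <- seq(50, 290, by = 40)
  sp <- mk_spikes(
    c(rep(1, length(pre)), 1, rep(2, length(pre) + 3), 3, 3, 3),
    c(pre, 470,                      # cell 1: 180 ms gap vs 40 ms pre-ISI
      pre, 310, 345, 370,            # cell 2: resumes 25 ms after its last
      100, 200, 355),                # cell 3: two pre-ISIs only
    cells = cells)
  out <- detect_burst_pause(sp, 1:3, stim = c(300, 350))
  expect_equal(out$label, c("pause", "none", "undetermined"))
})

test_that("EI and CS follow their definitions on a toy map", {
  m <- compute_EI_CS(c(10, 4, 0), c(8, 6, 2), c(8, 10, 8))
  expect_equal(m$EI, c(0, -4, -6))
  expect_equal(m$CS_raw, c(10, 8, 6))
  expect_equal(m$CS, c(1, 0.8, 0.6))
  expect_true(all(abs(m$CS) <= 1))
  expect_true(all(!(m$center & m$surround)))
  expect_equal(m$center_area, 1)       # all three pixels exceed 0.5
  ## in_off == con at T2 -> EI = 0, CS = FR_con(T1) before normalization
  m2 <- compute_EI_CS(c(3, 1), c(5, 5), c(5, 5))
  expect_equal(m2$EI, c(0, 0))
  expect_equal(m2$CS_raw, c(3, 1))
  ## all-zero map: normalization skipped and flagged
  m3 <- compute_EI_CS(c(0, 0), c(0, 0), c(0, 0))
  expect_false(m3$normalized)
})

test_that("CS map computation commutes with pixel permutation", {
  set.seed(1)
  t1 <- runif(20); t2 <- runif(20); toff <- runif(20)
  perm <- sample(20)
  a <- compute_EI_CS(t1, t2, toff)
  b <- compute_EI_CS(t1[perm], t2[perm], toff[perm])
  expect_equal(b$CS, a$CS[perm])
  expect_equal(b$center, a$center[perm])
})

test_that("coherence index is the mean absolute correlation", {
  expect_equal(coherence_index(1), 1)
  expect_equal(coherence_index(rep(0, 7)), 0)
  expect_equal(coherence_index(c(-0.5, 0.5)), 0.5)
  expect_equal(coherence_index(numeric(0)), 0)
})

test_that("correlograms find periodicity and peak at zero lag", {
  ## a 2 Hz periodic train: autocorrelation peaks at 500 ms lag
  t <- seq(0, 4999, by = 500) + rep(c(0, 3), length.out = 10)
  ac <- correlogram(t, t, bin = 10, max_lag = 2000, T_sim = 5000)
  expect_equal(which.max(ac$cor), which(ac$lag == 0))
  expect_equal(ac$dominant_freq, 2, tolerance = 0.1)
  expect_gt(ac$coherence, 0)
  ## cross-correlation of a delayed copy peaks at the delay
  cc <- correlogram(t, t + 50, bin = 10, max_lag = 500, T_sim = 5000)
  expect_equal(cc$lag[which.max(cc$cor)], 50)
  expect_error(correlogram(numeric(0), t), "empty")
})

test_that("burst-pause false positives on Poisson trains match the 2-sd rule", {
  ## dual route: the same 2-sd rule applied directly to raw exponential
  ## intervals (oracle) vs the packaged detector run on the spike trains
  set.seed(42)
  n_rep <- 400
  cells <- data.frame(cell_id = 1, type = "PC")
  det <- orc <- logical(n_rep)
  keep <- rep(TRUE, n_rep)
  for (k in seq_len(n_rep)) {
    t <- cumsum(rexp(120, rate = 0.05))  # 50 Hz homogeneous Poisson
    t <- t[t < 1000]
    sp <- mk_spikes(rep(1, length(t)), t, cells = cells)
    out <- detect_burst_pause(sp, 1, stim = c(300, 300.0001))
    if (out$label == "undetermined") { keep[k] <- FALSE; next }
    det[k] <- out$label %in% c("pause", "burst_and_pause")
    pre <- diff(t[t < 300])
    nxt <- t[t >= 300.0001]
    last <- max(t[t < 300.0001])
    gap <- if (length(nxt)) nxt[1] - last else max(t) - last
    orc[k] <- gap > mean(pre) + 2 * sd(pre)
  }
  expect_identical(det[keep], orc[keep])
  ## and the empirical rate sits in the tail region the rule implies
  ## (exp(-3) ~ 5% for known parameters, inflated by estimation noise)
  p_hat <- mean(det[keep])
  expect_gt(p_hat, 0.01)
  expect_lt(p_hat, 0.30)
})
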