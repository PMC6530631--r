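---
title: "Reconstructing and simulating a cerebellar microcircuit scaffold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and simulating a cerebellar microcircuit scaffold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerescaffold)
```

The package rebuilds a block of cerebellar cortex plus its deep-nuclei
target as three decoupled stages — cell placement, connectome construction,
and spiking simulation — followed by the analyses used to validate each
stage.  This vignette records the model itself, every tunable that matters,
and the design decisions taken where the problem was genuinely open.

## Coordinate frame and volumes

A fixed axis convention is used throughout: `x` is parasagittal
(mediolateral), `y` is vertical with 0 at the bottom of the granular layer,
and `z` is transversal — the direction parallel fibers run.  The reference
cortical volume is a 400 x 400 um^2 base of height 330 um, split into a
granular layer (0–150 um), the Purkinje-cell layer (150–180 um), and the
molecular layer (180–330 um), whose lower and upper halves host basket and
stellate cells respectively.  A 200 x 200 x 600 um^3 deep-cerebellar-nuclei
(DCN) block sits logically below the slab, centered under the base (the
anatomy gives no lateral registration, so centering is a convention; all DCN
connectivity is distance-flat for the same reason).

Seven cell types are placed: Golgi (GoC), glomeruli (Glom — mossy-fiber
terminals treated as relay elements), granule (GrC), Purkinje (PC), basket
(BC), stellate (SC) and DCN cells (DCNC), with per-type volumetric densities
(planar for PCs) and soma radii held in `scaffold_config()`.

## Cell placement

### Bounded self-avoiding random walk

All populations except PCs and DCNCs are laid out in thin horizontal
sublayers of height 1.5 soma diameters.  Within a sublayer the walk places
the first soma uniformly and advances by one soma diameter plus a scatter
term `s` drawn from a normal distribution centered on
`epsilon = (3 / (4 pi rho))^(1/3) - r` (the compound-sphere radius minus the
soma radius, `compute_epsilon()`), truncated to `[0.75, 1.25] epsilon`, along
a uniform planar angle.  The vertical coordinate is drawn uniformly inside
the sublayer.

Two overlap rules are enforced simultaneously: in-plane distance at least one
soma diameter against cells of the same sublayer (the walk is planar there),
and full 3D distance at least one soma diameter against every other
sublayer.  The second rule guarantees the package-wide invariant that no two
somata of a population overlap in 3D, which the test suite checks by
brute-force all-pairs scans.

Two bounds keep the walk's behavior controlled:

* **Retry budget.**  A candidate is redrawn up to 200 times before the walk
  restarts from a fresh uniform point; a sublayer is declared saturated after
  2000 consecutive restarts that fail to place a single cell.  Under this
  budget the dense granule layer jams close to its random-sequential-packing
  limit: roughly 87,000 of the 93,600 nominal granule cells fit, a ~6%
  shortfall that is a physical property of non-overlapping placement at this
  density, not an algorithmic artifact.  All other populations reach their
  nominal counts exactly.
* **Segment length.**  Every 10 accepted placements the walk restarts from a
  fresh uniform point.  An unbroken walk is a diffusion: at low densities
  (glomeruli, Golgi cells) it would wander inside a local cloud and leave
  most of the layer empty.  Finite segments keep the walk's local spacing
  statistics — each cell still sits one diameter plus `epsilon` from its
  predecessor — while uniformly scattered segment origins give uniform
  occupancy of the layer, which the connectivity stage depends on.

### Purkinje cells

PC somata form a staggered planar lattice in the 30 um PC layer.  Rows run
along `x` at a `z` pitch of one dendritic slab width (30 um), so adjacent
parasagittal dendritic slabs abut without overlapping; the `x` pitch is
`1 / (density * slab width)` (~74 um at the reference density) and alternate
rows are offset by half a pitch.  The observed scatter of real PC positions
(an average ~5 degree angular shift between neighbours) is realized as
per-cell Gaussian `x` jitter with sd `30 tan(5 deg)` ~ 2.6 um, plus uniform
`y` noise within the layer.  The quincunx diagonal spacing
`sqrt(30^2 + 37^2)` ~ 47.6 um reproduces the first maximum of the PC
pairwise-distance distribution (~49 um), with further maxima at the lattice
harmonics.

### DCN cells and ascending axons

The 12 DCNCs are placed by uniform rejection sampling with soma non-overlap;
a random walk adds nothing at n = 12.  Every granule cell receives an
ascending-axon (aa) height drawn from a Gaussian of mean 181 um and sd 66 um,
resampled while non-positive and truncated above at the pial surface; the aa
tip height is also the vertical coordinate of the cell's parallel fiber (pf).
The truncation rule at the pia is an assumption — the anatomy constrains the
distribution range, not its upper tail behavior.

### Validation by pairwise-distance KDE

`kde_pairwise_distances()` estimates the density of all 3D inter-soma
distances of a population with a Gaussian kernel of fixed per-population
bandwidth.  The bandwidth is chosen by the Sheather–Jones plug-in rule on a
bounded subsample of distances: it resolves the multimodal lattice structure
of the PC population (Silverman's rule, ~18 um here, smears the first
lattice peak away) while remaining smooth for the homogeneous populations.
Because the pair-distance density of a box-uniform population has a broad,
flat top, local maxima are filtered for prominence (a peak must rise at
least 2% of the global maximum above the saddle separating it from higher
peaks) so that subsampling wiggles are not reported as structure.  For
populations beyond ~1.4 million pairs a uniform random subsample of pairs is
used.

## Connectome construction

Sixteen connection types are built by *intersection rules* — a pre-synaptic
axonal field intersecting a post-synaptic dendritic field, both modeled as
geometric primitives (spheres, cylinders, boxes, slabs, lines) — followed by
pruning to configured convergence (mean afferents per target) or divergence
(mean efferents per source) ratios.  The geometry per rule:

| rule | geometry |
|---|---|
| Glom-GrC | 3D distance <= 40 um (maximum granule dendrite reach) |
| Glom-GoC | glom inside the GoC basolateral cylinder (radius 50 um, below the soma) |
| GoC-Glom | glom inside the GoC axonal box (x, z within 160 um, granular layer) |
| GoC-GoC | soma distance <= 160 um, no self-pairs |
| aa-GoC | GrC under the basolateral cylinder with aa tip reaching the soma height |
| pf-GoC | pf crosses the apical cylinder: dx <= 100 um, pf in the molecular layer |
| SC-SC, BC-BC | soma distance <= 100 um, no self-pairs |
| pf-SC, pf-BC | pf within 15 um of the soma in x and height, dz <= 200 um |
| SC-PC | on-beam axon: dx <= 30 um, dz <= 150 um |
| BC-PC | off-beam axon: dx <= 150 um, dz <= 30 um |
| aa-PC | near-apposition to the dendritic plane: dz <= 4 um, dx <= 150 um, tip in the molecular layer |
| pf-PC | dx <= 150 um (slab radius), pf in the molecular layer |
| PC-DCNC, Glom-DCNC | all pairs (volumes unregistered), random pruning |

All pf rules additionally bound the transversal reach to `|dz| <= 200 um`,
half of the 400 um maximum fiber length per side.  The aa-PC `dz` tolerance
of 4 um represents direct apposition of the vertical axon to the quasi-planar
PC dendritic tree (about a granule soma radius plus spine reach); with PC
slabs tiling `z` at a 30 um pitch, this makes `8/30` of granule positions
z-eligible and, combined with the probability that the aa tip reaches the
molecular layer, yields ~21% of granule cells eligible to contact a PC —
the anatomically expected fraction.  A looser tolerance (e.g. the 15 um
half-slab) would make essentially every granule cell eligible, which is
inconsistent with that fraction.

### Pruning

For each target cell, `prune_candidates()` draws exactly
`min(target, n_candidates)` partners without replacement with probability
proportional to an anisotropic Gaussian kernel
`exp(-(dx/lx)^2 - (dy/ly)^2 - (dz/lz)^2)`, implemented with exponential race
keys over a deterministically ordered candidate table, so a fixed seed gives
a bit-identical connectome.  Per-axis decay lengths default to the rule's
geometric extent along that axis; the Glom-GrC rule instead uses 10 um —
the scale of a granule dendrite — so that selection is biased toward
dendrite-reach gloms rather than uniform over the 40 um ball.  The realized
mean dendrite length (inter-soma distance minus the granule and glomerulus
radii) is then ~11-12.5 um, in the anatomical range; a distance-flat
selection would give ~23 um.  Quoted granule dendrite lengths are
surface-to-surface quantities: even an exact nearest-4 selection has a mean
*inter-soma* distance near 13.5 um in this volume.

When geometry yields fewer candidates than the target (volume borders, low
glomeruli under a deep Golgi soma), all candidates are accepted; there are
no periodic boundaries and no invented edges.  Golgi-to-granule inhibition
is not built directly: GoC-Glom edges are fused with Glom-GrC edges
(`fuse_goc_glom_grc()`) — a Golgi cell inhibits a granule cell through any
shared glomerulus, duplicates collapsed, distance recomputed between the
somata.

### Convergence/divergence targets

The ratios are configuration values, not constants of the method.  Defaults
(per `scaffold_config()`): Glom-GrC convergence 4 (one glomerulus per
dendrite), Glom-GoC 20, GoC-Glom divergence 20, GoC-GoC 10, aa-GoC 150,
pf-GoC 1200, SC-SC and BC-BC 4, pf-SC and pf-BC 600, SC-PC and BC-PC 6,
aa-PC 100, pf-PC 5000, PC-DCNC 69, Glom-DCNC 15.  Where the cited anatomy
pins a number (Glom-GrC 4) it is used directly.  The remainder are
order-of-magnitude anatomical values calibrated jointly so that the
reference network reproduces the expected activity regime of this circuit
(granule baseline ~2 Hz, Purkinje baseline ~55 Hz and burst response
~250 Hz, DCN silencing during the burst): in a reduced volume the absolute
ratios necessarily scale with the available partner pools, so activity is
the observable that disciplines them.  Two cases deserve note:

* **PC-DCNC convergence = 69 (all PCs).**  The anatomical convergence of
  Purkinje cells onto one DCN neuron is in the hundreds, far more than the
  ~70 PCs this volume contains, so every PC projects to every DCNC.  At the
  table weight (-0.0075 nS) anything much sparser cannot silence the DCN
  during the burst.
* **aa-PC convergence = 100.**  Geometry alone admits ~1000 aa contacts per
  PC here; at the 75 nS aa weight that would saturate PCs far above their
  physiological baseline, so the aa-PC rule is pruned like the other
  excitatory inputs while the 21% eligibility statistic remains a pure
  geometry readout.

`ratio_report()` summarizes achieved in/out-degrees against the targets and
regresses achieved on configured values across connection types, for both
axes; divergence targets not set directly are implied by the convergence
target and the population sizes.

## Network simulation

Each non-glomerulus cell is a conductance-based leaky integrate-and-fire
unit with exponential synapses:

$$C_m \frac{dV}{dt} = -\frac{C_m}{\tau_m}(V - E_L) + I_e
  + g_e (E_e - V) + g_i (E_i - V),$$

with per-type parameters (capacitance, time constant, rest, refractory
width, intrinsic current, reset, threshold, excitatory and inhibitory decay
constants) from the configuration tables.  Conductances decay exactly
(`exp(-dt/tau)` per step) and jump by `|w|` on delayed spike arrival, with
the channel selected by the sign of the weight; the membrane advances by
exponential Euler with conductances frozen over the 0.1 ms step.  Threshold
is detected at step boundaries, spikes are stamped at end-of-step, the
membrane is reset and clamped for the refractory period, and synaptic delays
are rounded to the nearest step.  Reversal potentials are not part of the
printed parameter tables; the conventional conductance-LIF values
`E_e = 0 mV`, `E_i = -85 mV` are used and exposed in the configuration.

Glomeruli are parrot relays: they emit exactly the imposed stimulus times
and propagate them through their efferent synapses.  All integration state
starts deterministically (membranes at rest), so identical seeds give
bit-identical spike records; a side effect is that same-type pacemakers
(notably the 12 DCNCs, which share parameters and receive nearly identical
inputs) stay phase-locked, visible as zero variance in their baseline rates.

The engine is a single C++ loop over steps and neurons with a ring buffer of
future conductance increments; the full reference network (about 96,000
units and 1.8 million synapses) simulates one biological second in roughly
half a minute on one core.

### Stimulation protocols

* **Default burst** (`default_protocol()`): 1000 ms total; 1 Hz independent
  Poisson background on every glomerulus (independence matches the per-glom
  rate variance of the reference regime); at 300 ms a 150 Hz burst lasting
  50 ms is added to every glomerulus inside a 140 um-radius vertical
  cylinder through the granular layer, centered on the base.  A cylinder is
  used rather than a sphere because mossy-fiber bundles traverse the full
  layer depth, and the expected enclosed count (~2,800 of ~7,200) then
  matches the stimulated fraction this volume is known to produce.  The
  burst is a regular train whose first spike falls at onset:
  `floor(duration * rate) = 7` spikes, i.e. ~140 Hz measured over the
  window.  Starting at onset also matters dynamically: it lets
  feed-forward PC inhibition reach the DCN before the synchronized DCNC
  pacemaker crossing that otherwise falls early in the window.
* **Center-surround pair** (`cs_protocol()`): the same burst restricted to
  the 40 glomeruli nearest the center, run in control and with
  Golgi-to-granule inhibition switched off; granule rates are then compared
  in windows 0–20 ms (T1) and 20–40 ms (T2) after onset.
* **Oscillation regime** (`oscillation_protocol()`): 5000 ms of 5 Hz
  background with the pf-GoC weight raised to 30.4 nS and no burst.
* **Orthogonal plexus** (`orthogonal_plexus_protocol()`): connectivity
  rebuilt with the SC and BC axonal fields swapped and the burst
  concentrated in a 30 um radius.

Switch-off experiments (`apply_switch_off()`) zero the weights of named
connection types while keeping the edges, so they compose and invert
exactly.

## Analyses

* `mean_rates()` — per-cell and per-population rates in the baseline
  (pre-stimulus), during-stimulus, and steady-state windows; the steady
  state is the last 300 ms of the run.
* `classify_response()` — a cell is excited if its during rate at least
  doubles the baseline (granule cells must additionally fire more than one
  spike during the stimulus, excluding background singletons), inhibited if
  it at most halves it; silent-baseline cells can only be excited.
* `detect_burst_pause()` — a Purkinje pause is a first post-stimulus
  inter-spike interval exceeding the pre-stimulus ISI mean by more than two
  pre-stimulus ISI standard deviations.  The mean offset matters: a bare
  2-sd threshold degenerates for near-regular trains, where the sd
  vanishes and every interval would count as a pause.  Cells with fewer
  than three pre-stimulus ISIs are flagged undetermined.
* `compute_EI_CS()` — pixelwise `EI = FR_con(T2) - FR_inoff(T2)` and
  `CS = FR_con(T1) - EI`, CS normalized by its maximum absolute value;
  center pixels have CS > 0.5, surround CS < -0.5, and relative areas are
  pixel-count fractions.  `grc_rate_map()` supplies the rate maps on a
  10 um grid over the granular layer (granule cells binned by soma
  position); the pixel size resolves the ~50 um center at several pixels
  while keeping ~10 cells per pixel.
* `correlogram()` — normalized cross-correlation of mean-subtracted binned
  spike counts (10 ms bins, lags to 2000 ms: enough to resolve rhythms well
  below 1 Hz while still sampling the fast granular-loop period), with the
  coherence index `C = sum(|A_n|)/len(A)` and the dominant frequency read
  from the first positive-lag local maximum.  `oscillation_subset()`
  returns the Golgi cells sharing at least one parallel-fiber afferent
  granule cell, plus those granule cells.

## Numerical and degenerate-input conventions

Candidate tables are sorted deterministically before any random draw; all
randomness derives from one master seed per stage expanded into child seeds,
so every stage can be regenerated independently and the full pipeline is
bit-reproducible.  Degenerate situations are reported rather than patched:
saturated placement returns the achieved count with a warning, pruning
shortfalls keep all candidates, an all-zero CS map skips normalization and
says so, a single-type ratio regression is flagged as degenerate, and
non-finite membrane state aborts the simulation naming the neuron.

## What the reconstruction does and does not capture

The scaffold generates its own inputs — there is no external data set — so
what the tests demonstrate is internal consistency of the three stages plus
agreement with the anatomical and physiological statistics the circuit is
known to exhibit at this scale (cell counts and spacings, wiring ratios,
burst responses, DCN inversion).  Real tissue differs in ways the model does
not represent: morphological dendrites and axons (fields here are geometric
primitives), synaptic short-term dynamics and plasticity, cross-type soma
exclusion (only same-type overlap is forbidden), the inferior olive, and any
neuromodulation.

One dynamical limitation deserves emphasis.  In the oscillation regime the
granular layer synchronizes at the period set by its loop delays and decay
constants — pf delay 5 ms, Golgi-to-granule delay 2 ms, 10 ms inhibitory
decay — i.e. at roughly 20–50 Hz.  The point-neuron model contains no
slower process (no adaptation currents, no slow GABA kinetics, no
short-term depression), so sub-2 Hz collective rhythms of the kind seen in
vivo do not emerge from this parameter set, and analyses that look for them
will instead find the loop frequency.  Reproducing slow oscillations would
require adding a slow biophysical timescale to the neuron or synapse models.

## Problem sizes used by the tests

The unit and property tests run on reduced volumes (1/16 to 1/32 of the
reference base area, a few thousand cells) that exercise every code path in
seconds.  The reference-scale checks build the full 400 x 400 um^2 volume —
about 96,000 cells and 1.8 million synapses — across five placement seeds,
one full connectome, one full burst simulation, and one oscillation run on a
half-area volume; the same sizes are used by `scripts/acceptance.R`.
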