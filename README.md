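# cerescaffold

Scaffold reconstruction and spiking simulation of the cerebellar
microcircuit in R.

The cerebellar cortex has a quasi-crystalline architecture — granule cells
whose ascending axons bifurcate into transversal parallel fibers, flat
parasagittal Purkinje dendritic trees, on-beam stellate vs off-beam basket
axons, Golgi feedback inhibition, and a deep-nuclei (DCN) output stage
inverted by Purkinje inhibition.  `cerescaffold` rebuilds a 0.077 mm^3
block of this circuit from statistical rules rather than reconstructed
morphologies, for computational neuroscientists who want a controllable,
fully reproducible microcircuit model:

1. **Placement** — density-driven 3D positioning of seven cell types
   (~96,000 cells): a bounded self-avoiding random walk in thin sublayers
   for most types, a staggered planar lattice for Purkinje cells, with
   per-population soma non-overlap and ascending-axon heights drawn from a
   truncated Gaussian (181 +/- 66 um).
2. **Connectivity** — 16 connection types from axonal/dendritic field
   intersection followed by pruning to convergence/divergence targets with
   anisotropic distance-decay probabilities (~1.8 million synapses),
   including the Golgi-to-granule fusion through shared glomeruli.
3. **Simulation** — conductance-based exponential-synapse
   leaky integrate-and-fire dynamics at 0.1 ms resolution,

   `C_m dV/dt = -(C_m / tau_m)(V - E_L) + I_e + g_e(E_e - V) + g_i(E_i - V)`,

   with glomeruli as parrot relays of the imposed mossy-fiber stimulus
   (Poisson background plus localized 150 Hz bursts), in a compiled engine
   (one biological second of the full network in ~30 s on one core).
4. **Analysis** — PSTHs, excited/inhibited classification, Purkinje
   burst-pause detection, center-surround excitatory-inhibitory maps, and
   population correlograms with a coherence index.

The methods vignette (`vignettes/scaffold-methods.Rmd`) documents the model,
its parameters and the design decisions in detail.

## Worked example

A reduced volume (1/16 of the reference base area) runs the whole pipeline
in a few seconds:

```r
library(cerescaffold)

cfg <- make_fixture(1 / 16)          # 100 x 100 um^2 base, same densities
p   <- place_cells(cfg, seed = 1)
#> Warning: placement saturated: 5784 of 5850 cells placed
p
#> Scaffold placement: 6329 cells (seed 1 )
#>      type     N
#> 1:    GoC    14
#> 2:   Glom   450
#> 3:    GrC  5784
#> 4:     PC     4
#> 5:     BC    38
#> 6:     SC    38
#> 7:   DCNC     1
```

The warning is expected: the granule layer jams slightly below its nominal
density, exactly as the full-scale reconstruction does (~6% shortfall).

```r

cn <- build_connectome(p, seed = 1)
sp <- run_protocol(p, cn, default_protocol(cfg), seed = 1)
mean_rates(sp)
```

`place_cells()` returns the soma table (id, type, x/y/z in um) plus the
per-granule-cell ascending-axon heights; `build_connectome()` returns one
edge table (pre id, post id, 3D inter-soma distance) per connection type;
`run_protocol()` simulates one second of the default experiment — 1 Hz
mossy-fiber background with a 150 Hz, 50 ms burst at t = 300 ms — and
returns the spike record.  `mean_rates()` then reports per-population mean
firing rates before, during and after the burst, and
`classify_response()` splits each population into excited/inhibited
subgroups.  At the full reference scale (`scaffold_config()`), granule
cells sit near 2 Hz at baseline, excited granule cells reach ~110 Hz during
the burst, excited Purkinje cells ~250 Hz, and all 12 DCN cells are
silenced by convergent Purkinje inhibition — the circuit's sign inversion.

A thin command-line pipeline over the same functions is installed at
`inst/cli/scaffold.R` (`validate-config`, `place`, `connect`, `simulate`,
`analyze`).

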