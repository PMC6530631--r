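Package: cerescaffold
Title: Scaffold Reconstruction and Spiking Simulation of the Cerebellar
    Microcircuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a scaffold model of the cerebellar cortex and deep
    cerebellar nuclei: density-driven 3D placement of seven cell types
    (bounded self-avoiding random walk, planar Purkinje grid), geometric
    intersection plus convergence/divergence pruning to generate a 16-type
    connectome, conductance-based leaky integrate-and-fire network
    simulation with parrot-relay mossy fiber glomeruli, and the validation
    analyses (pairwise-distance kernel density estimates, PSTH,
    excited/inhibited classification, Purkinje burst-pause detection,
    center-surround excitatory-inhibitory maps, and population coherence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
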