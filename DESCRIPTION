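Package: scwavemap
Title: Retinal-Wave-Driven Development of Orientation Maps in the Superior Colliculus
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates stage III retinal waves on a two-layer retina to
    superior-colliculus (SC) lattice and refines ON/OFF retinocollicular
    synaptic weights with Hebbian plasticity under subtractive normalization.
    Waves propagate away from stochastically sampled asymmetric-inhibition
    sources, OFF retinal ganglion cells fire with a delay relative to ON
    cells, and the resulting correlations segregate ON/OFF receptive
    subfields of SC neurons. The package builds difference-of-Gaussians
    receptive fields, extracts orientation preference maps by Fourier
    analysis, and quantifies map structure (tuning strength, gOSI, ON/OFF
    segregation, local homogeneity, wave-flow fields, map singularity, and
    alignment to the concentric angles of the visual field), together with
    config-driven reproductions of the model experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
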