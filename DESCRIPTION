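Package: olfsim
Title: Spiking-Network Simulation of the Early Drosophila Olfactory System
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates the first two stages of the fruit-fly olfactory
    pathway: odorant transduction, leaky integrate-and-fire olfactory
    receptor neurons (ORNs) with spike-rate adaptation and non-synaptic
    ("ephaptic") interactions between ORNs co-housed in a sensillum, and a
    two-glomerulus antennal lobe with projection neurons and lateral
    inhibitory local neurons.  Includes deterministic stimulus generators
    (steps, ramps, parabolas, triangular pulses), a naturalistic
    odor-plume generator with power-law whiff and blank durations and
    Gaussian-copula inter-odorant correlation, and analysis tools for
    spike-density functions, mixture-ratio encoding error, plume
    correlation encoding, and ORN dynamic range.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
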