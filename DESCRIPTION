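Package: corrinv
Title: Correlation-Invariant Synaptic Plasticity Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and analysis tools for a family of Hebbian synaptic
    plasticity rules that combine nonlinear long-term potentiation, linear
    long-term depression and a homeostatic metaplasticity factor, making
    feature learning invariant to second-order input correlations. Provides
    seeded generators for grouped sparse/Gaussian rate inputs, circular
    population-coding stimuli and spatially correlated synthetic image
    patches; single-neuron and recurrently inhibited population trainers;
    a leaky integrate-and-fire spiking network with triplet
    spike-timing-dependent plasticity; and metrics including whitening,
    signal-to-noise ratios, tuning-curve widths, linear Fisher information
    and receptive-field localization.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    jsonlite,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
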