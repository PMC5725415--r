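Package: rulkovfield
Title: Modified Rulkov Map Neurons, Rate Reduction, and Augmented Neural Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for a modified Rulkov map neuron
    whose slow adaptation variable is driven by a binary spike indicator.
    Provides the discrete-time single-neuron simulator with spike detection,
    analysis of the fast subsystem (fixed points, limit-cycle periods, and the
    staircase firing-rate function with its discontinuity points), closed-form
    subthreshold frequency responses of the map and of its rate reduction,
    integration of the one-dimensional rate-reduced adaptation equation, the
    expected firing rate under Gaussian threshold noise together with its
    error-function-sum approximation and fitting, a two-population neural
    field on (-1,1) with exponential connectivity kernels, and a matched
    all-to-all spiking network with exponential synapses and threshold noise.
    Includes a stimulus generator, scenario presets for canonical spiking
    patterns (tonic spiking, spike-frequency adaptation, rebound,
    accommodation, first-spike latency, inhibition-induced spiking),
    delimited-text trace input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
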