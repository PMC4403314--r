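Package: spikefit
Title: Evolutionary Parameter Estimation for Spiking Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits adaptive integrate-and-fire spiking neuron models (IF, aIF,
    atIF, aEIF, a2EIF, Izhikevich/aQIF) to spike-train data with a hybrid
    genetic algorithm whose fitness is the van Rossum spike-train distance,
    evaluated at a timescale that anneals geometrically across generations.
    Includes exact exponential-kernel van Rossum machinery (brute-force and
    sorted-merge algorithms), the coincidence factor and intrinsic
    reliability, expected coincidence and van Rossum values against
    inhomogeneous Poisson rate models, spectro-temporal receptive field
    (STRF) estimation by normalized reverse correlation with an SVD
    regularized pseudo-inverse, an STRF-to-neuron cascade model fitted by
    tandem evolution of the receptive-field and neuron-parameter
    populations, synthetic data generators for current-injection and
    auditory-style experiments, plain-text file formats, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
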