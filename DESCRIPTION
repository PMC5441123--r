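Package: mibci
Title: Motor-Imagery Brain-Computer Interface Toolkit with Temporal ICA,
    One-Versus-Rest CSP and Shared-Control Gaming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a hybrid motor-imagery
    brain-computer interface entirely on synthetic EEG/EOG. Includes a
    trial-scheduled autoregressive EEG/EOG generator with class-dependent
    ERD/ERS band-power modulation, preprocessing (notch, ocular regression,
    common average reference, Chebyshev-I filterbank), characteristic-
    component selection by between-class R-squared, an independent component
    analysis that preserves temporal structure by modelling sources
    autoregressively and minimising residual dependence with a natural
    gradient, one-versus-rest common spatial patterns with log-variance
    features, a small-world neural network classifier with gray-code/idle
    decoding, a finite-state-automaton shared-control strategy driving a
    headless 3D falling-blocks game, and cross-validated pipeline
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    e1071,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
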