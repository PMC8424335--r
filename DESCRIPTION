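Package: dsfnet
Title: Dynamical Structure Function Reconstruction for Genetic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network reconstruction for synthetic gene circuits measured with
    incomplete state information. Derives the dynamical structure function
    (Q(s), P(s)) of a circuit model by eliminating hidden states (e.g. mRNA)
    from a linearization, estimates it directly from time-series perturbation
    data via structured ARX regression with discrete-to-continuous conversion,
    and quantifies designed-versus-crosstalk edges as time- and
    frequency-dependent functions (impulse-response kernels, H-infinity and H2
    gains). Includes benchmark circuit models (incoherent feedforward loops
    with and without protease-loading crosstalk, a transcriptional event
    detector, a cyclic three-node repressor), a perturbation-experiment
    simulator, and CSV/JSON/DOT/GraphML interchange formats with a command-line
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
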