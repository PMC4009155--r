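Package: neurokernel
Title: Tensor-Product Kernels for Multiscale Neural Decoding and Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decoding and closed-loop control of multiscale neural activity
    with reproducing-kernel methods. Spike trains enter through Schoenberg
    kernels on smoothed intensity functions, local field potentials through
    Schoenberg kernels on windowed traces; direct-sum kernels pool units and
    channels and a tensor-product kernel fuses the two modalities. An online
    quantized kernel least-mean-square (Q-KLMS) learner provides stimulus
    decoders, and a filtered-error adaptive inverse controller optimizes
    multichannel microstimulation patterns that reproduce target neural
    responses. A seeded synthetic neural plant (inhomogeneous-Poisson spiking,
    impulse-response field potentials) makes the whole pipeline runnable and
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
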