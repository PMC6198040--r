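Package: mtnet
Title: Self-Organization of Dynamic Microtubule-Motor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based Brownian-dynamics simulation of dynamic microtubules
    and two-headed crosslinking motors in a thin periodic box, together with
    the analysis pipeline that classifies the emerging networks. Motor
    crosslinks are classified into end-end (V), end-side (T) and side-side
    (parallel, anti-parallel, crossing) types; an aster-strength order
    parameter (largest V-link cluster fraction, c_max) and a polarity-sorting
    parameter (P) label each network as polar (aster) or nematic. Includes an
    extensile-behavior metric based on the minus-end velocity-polarity
    correlation, phase-space scans with a dimensionless-control-parameter
    collapse score, synthetic geometry fixtures, and the closed-form theory of
    the motor distribution along a single growing filament with
    method-of-lines and stochastic validators.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    igraph,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
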