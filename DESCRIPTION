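Package: myoflow
Title: Blood Flow Dynamics in Myogenically Active Cerebral Arterial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale simulation of one-dimensional blood flow in networks of
    small cerebral arteries whose walls develop pressure-induced myogenic tone.
    A linearized pressure-flow haemodynamics solver is coupled, weakly or
    strongly (fixed-point iteration), to a layered smooth-muscle-cell
    chemo-mechanical wall model: pressure-driven intracellular signalling sets
    cross-bridge phosphorylation and cytoskeletal remodelling, which drive
    actin-myosin filament sliding, wall tone, luminal area and compliance.
    Includes builders for symmetric arterial trees, pressure signal generators,
    and scripted numerical experiments (pressure steps, numerical-settings
    comparisons, autoregulation curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
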