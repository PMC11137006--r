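Package: cartsim
Title: Agent-Based Simulation of CAR T-Cell Therapy on Heterogeneous Tumour Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multiscale agent-based simulator of tumour-derived organoids
    under chimeric antigen receptor (CAR) T-cell immunotherapy.  Cancer cells
    are off-lattice agents with a stochastic four-phase cell cycle whose
    progression scales with a heritable oncoprotein expression level and local
    oxygen; CAR T-cell agents chemotax up an immunostimulatory-factor gradient
    by a biased random walk, adhere to antigen-presenting targets, attempt
    kills, and exhaust stochastically.  The microenvironment is a vector of
    reaction-diffusion equations solved implicitly on a voxel mesh with
    Dirichlet nodes.  Experiment presets cover dose scans, long-term
    persistence, multiple dosing and multi-antigen recognition, with tidy
    metrics tables, kill ledgers and point-cloud snapshots.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
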