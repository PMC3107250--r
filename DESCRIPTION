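Package: npcbd
Title: Coarse-Grained Brownian Dynamics of Transport Through the Nuclear
    Pore Complex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a two-spoke, cross-sectional bead-spring model of the
    nuclear pore complex (NPC): an elastic scaffold anchored to a rigid
    nuclear envelope by pom springs, with grafted FG-repeat domains modelled
    as discrete wormlike chains. Simulates karyopherin-mediated cargo import
    with an explicit overdamped Langevin integrator in reduced units
    (kT, nm, 0.1 ns), using hydrophobic kap-FG and FG-FG pair potentials, a
    soft excluded-volume repulsion, and Ottinger's rejection scheme for
    finite chain extensibility. Detects transport events (first kap-FG
    contact at the cytoplasmic filaments through complete loading into the
    nuclear basket) and computes the downstream statistics: first-passage
    time samples with inverse-Gaussian maximum-likelihood fits, radial
    occupancy histograms, hydrophobic bond lifetimes, binding-spot occupancy,
    shuttle counts, and selectivity experiments on intact versus
    filament-deficient pores.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
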