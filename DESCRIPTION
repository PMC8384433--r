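Package: compevol
Title: Two-Regime Phylogenetic Models of Trait Evolution with Competition
    and Biogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and maximum-likelihood inference for phylogenetic
    models of continuous trait evolution whose parameters differ between two
    regimes of lineages (for example tropical versus temperate breeders).
    Implements single- and two-regime Brownian motion, Ornstein-Uhlenbeck,
    early-burst, diversity-dependent and matching-competition processes;
    competition-aware models use stochastic maps of discrete regimes and of
    biogeographic occupancy to restrict interactions to sympatric lineages,
    and species means may carry observational error. Provides moment-based
    multivariate-normal likelihoods, AICc model selection with Akaike
    weights averaged over stochastic-map banks, Mk fitting and stochastic
    character mapping, tree slicing for large clades, range-overlap
    (Szymkiewicz-Simpson) sympatry scoring and downsampling, and fully
    seeded simulation harnesses for parameter-recovery and model-selection
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    stats,
    utils
Suggests:
    deSolve,
    jsonlite,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
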