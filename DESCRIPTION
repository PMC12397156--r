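Package: cdmstab
Title: Stability and Competition Inference for Delayed Multispecies
    Population Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discrete-time multispecies communities with delayed
    maturity and Beverton-Holt/Leslie-Gower competitive density dependence
    (the competitive delayed multispecies, CDM, model). Provides equivalent
    delayed and age-expanded simulators, closed-form interior and boundary
    equilibria, analytic Jacobians whose spectra depend only on equilibrium
    relative abundances, graph-theoretic (Gershgorin/Brualdi) sufficient
    stability conditions, spectral-radius scans over the relative-abundance
    simplex, Pianka niche-overlap estimation of competition coefficients,
    and a resilience-based optimisation that estimates the interspecific
    competition matrix from relative abundances alone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
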