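Package: gem2dmm
Title: Genome-Based Dynamic Metabolic Modelling of Anaerobic Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds calibrated dynamic metabolic models of batch fermentation
    from stoichiometric metabolic networks. Provides flux balance analysis on
    a built-in simplex solver, flux-consistent network reduction with
    protected metabolites, elementary flux mode enumeration by the
    double-description method, yield-space convex-hull selection of a minimal
    set of macroscopic reactions, and Monod/Contois ordinary-differential-
    equation models of carbohydrate fermentation with maximum-likelihood
    parameter estimation. Ships a synthetic reduced network and the published
    macroscopic-reaction stoichiometry for glucose fermentation by the
    cellulolytic rumen bacterium Fibrobacter succinogenes S85, together with
    a generator of simulated batch-culture time series for end-to-end
    testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    grDevices,
    jsonlite,
    lhs,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
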