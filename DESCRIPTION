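Package: cybgrowth
Title: Cybernetic and Monod Modelling of Multi-Substrate Bacterial Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits two competing models of batch bacterial growth
    on multiple lumped substrate pools: a Michaelis-Menten-Monod (MMM) kinetic
    model and a cybernetic model in which enzyme synthesis and activity are
    modulated by optimality-derived control variables. Parameters are estimated
    with a hybrid Nelder-Mead simplex / simulated-annealing optimizer, and
    competing fits are compared per species by Pearson correlation and AIC.
    Includes spline interpolation and growth-rate/lag analysis of biomass
    curves, hierarchical clustering of per-amino-acid depletion profiles into
    co-utilized groups, a Fisher's-Z co-expression coherence statistic for
    regulons, and a synthetic-data generator emulating a 19-amino-acid
    depletion experiment with four kinetic groups and triauxic growth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    cluster,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
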