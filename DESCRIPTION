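Package: page4dyn
Title: Phospho-Form Circuit Dynamics and Conformational Ensemble Metrics
    for the Disordered Protein PAGE4
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the PAGE4 phosphorylation circuit in prostate cancer
    cells, in which HIPK1-phosphorylated PAGE4 inhibits androgen receptor
    (AR) activity and AR represses the CLK2 kinase, closing a negative
    feedback loop that produces week-scale relaxation oscillations between
    androgen-dependent and androgen-independent phenotypes. Provides
    adaptive ODE integration of the five-species circuit, calibration of a
    default parameter set anchored to the 150-hour WT-PAGE4 half-life,
    treatment protocols (continuous androgen-deprivation therapy,
    intermittent ADT, bipolar androgen treatment), cohort simulations of
    unsynchronized cells with heterogeneity and phase-synchronization
    metrics, and oscillation analysis (period detection, quench time). A
    second component computes structural-order observables over C-alpha
    conformational ensembles of the 102-residue PAGE4 chain: radius-of-
    gyration free-energy profiles, pairwise distance distributions, contact
    maps, contact-based principal component analysis, and a geometric turn
    propensity; a constrained self-avoiding-walk generator supplies
    synthetic ensembles emulating the WT, HIPK1- and CLK2-phosphorylated
    forms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    deSolve,
    yaml,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
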