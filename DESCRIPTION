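Package: neurocascade
Title: Multitype Bellman-Harris Branching-Process Model of the Early Adult
    Hippocampal Neurogenic Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic and analytic modeling of the early stages of adult
    hippocampal neurogenesis as a multitype Bellman-Harris age-dependent
    branching process with shifted-gamma transit times. Provides forward
    event-based simulation of BrdU pulse-and-chase labeling curves, the
    renewal-equation expectation solver and stationary population state under
    Poisson influx, preprocessing of pulse-chase measurement tables
    (re-proportioning of double-labeled progenitor/neuroblast fractions and
    proportion-to-count transformation with propagated uncertainty), a
    genetic-algorithm calibration of model parameters by variance-weighted
    least squares, counterfactual prediction of neurogenesis under reduced
    apoptosis, and a synthetic pulse-chase experiment generator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
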