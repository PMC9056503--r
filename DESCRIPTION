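Package: petrv
Title: Proton-Activation PET Range Verification Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for positron-emission-tomography (PET) based range
    verification of low-energy proton beams in oxygen-18 enriched targets. Provides
    an analytic pencil-beam model (stopping power interpolation, CSDA range,
    layer-by-layer energy degradation, Gaussian spot fluence and surface-dose maps),
    an isotope-activation yield model for F-18 / N-13 / C-11 production in
    O-18-enriched tissue with inference of the O-18 enrichment fraction,
    constrained multi-exponential decay decomposition of 511-keV counting data with
    decay correction and washing-retention estimation, biological-washout fitting
    of dynamic PET time-activity curves, and seeded synthetic-data generators that
    emulate the corresponding counting experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
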