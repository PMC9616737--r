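Package: sgdyn
Title: Compartment Dynamics and Morphometry of Developing Sebaceous Glands
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying postnatal sebaceous-gland (SG) growth as a
    two-compartment progenitor/differentiated cell system.  The package
    integrates an ordinary-differential-equation model in which basal
    progenitors divide at a feedback-modulated, Gaussian-decaying rate and
    feed a suprabasal differentiated compartment; calibrates the free
    parameters (growth amplitude, feedback exponent, self-renewal
    probability) to observed cell counts by deterministic multistart
    optimisation; classifies parameter perturbations as progenitor-driven,
    differentiation-driven or combined gland expansion; estimates basal and
    suprabasal cell numbers from wholemount morphometry via ellipsoid
    surface-area and volume formulas; and ranks compartment marker genes by
    fold change after Gene Ontology adhesion-term filtering.  Synthetic-data
    generators emulate every input with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
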