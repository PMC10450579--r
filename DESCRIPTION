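Package: doubledrug
Title: Thermodynamic Linkage Analysis for Orthosteric-Allosteric
    Double-Drugging of Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative framework for combining an orthosteric (ATP-site)
    inhibitor with an allosteric modulator on a two-state protein kinase.
    Implements the conformational-selection linkage partition function
    (state populations, apparent dissociation constants, cooperativity
    factors and their thermodynamic-cycle symmetry), forward models and
    fitters for isothermal titration calorimetry (one-site and
    competitive-replacement), tight-binding fluorescence titrations, and
    coupled-enzyme inhibition readouts (four-parameter dose-response fits,
    IC50, dose-for-residual-activity and synergy grids), together with
    jackknife standard errors, global multi-condition linkage fits, seeded
    synthetic-data generators, named presets for the Aurora A/monobody and
    Abl/imatinib/SKI/asciminib systems, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
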