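Package: saltfec
Title: Salt-Dependent Elasticity and Secondary Structure of ssDNA from
    Force-Extension Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for optical-tweezers pulling experiments on
    single-stranded DNA. Converts force-distance traces to force-extension
    curves, fits semiflexible polymer-elasticity models (inextensible and
    extensible worm-like chain, extensible freely-jointed chain, and a
    tube-constrained thick chain for low-salt excluded-volume conditions),
    quantifies secondary-structure formation through a force-dependent
    effective contour length and a sigmoidal unpaired-fraction model, and
    analyses the scaling of the persistence length with ionic strength.
    Includes a seeded synthetic-trace generator emulating constant-velocity
    pulling in a harmonic trap so every stage of the pipeline can be
    validated by parameter-recovery simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
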