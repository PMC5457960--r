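Package: CephaloPLS
Title: Partial Least Squares Path Modeling for Cephalometric
    Treatment-Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A partial least squares path modeling (PLS-PM) engine with
    formative (Mode B) and reflective (Mode A) measurement blocks,
    centroid/factorial/path inner weighting schemes, communality and
    redundancy indices and the Tenenhaus goodness-of-fit criterion,
    together with a cephalometric measurement layer (Frankfort-horizontal
    and Sella-perpendicular reference geometry, signed landmark distances,
    occlusal vertical dimension, timepoint increments), the latent-variable
    model relating postsurgical occlusal vertical dimension to final
    mandibular setback in skeletal class III surgery-first cases, an
    inner-model search over candidate structural graphs, and calibrated
    synthetic-cohort generators for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
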