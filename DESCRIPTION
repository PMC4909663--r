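Package: peepabsorb
Title: PEEP Absorption in Mechanically Ventilated Patients with Auto-PEEP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulation and bedside-style analysis of what happens
    to total PEEP when external PEEP equal to 80 percent of auto-PEEP is
    applied during passive volume-controlled ventilation. Provides a
    compartmental RC lung model with an optional expiratory flow-limitation
    envelope, the full measurement protocol (end-inspiratory and
    end-expiratory occlusions, manual compression of the abdomen with
    flow-volume loop superposition), triplicate data-validation rules,
    complete/high/low PEEP-absorber classification, and the clinical
    prediction pipeline: univariate screening, VIF-pruned multiple logistic
    regression, multinomial secondary analysis, Youden threshold selection
    for respiratory rate, cross-validated discrimination and calibration,
    and diagnostic test metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
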