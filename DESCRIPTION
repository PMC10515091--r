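Package: leafzone
Title: Leaf-Trait Screening and Distribution-Zone Prediction for Bamboos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the northernmost hardiness zone of bamboo
    species from leaf morphological and anatomical indicators. Implements
    derivation of a 33-indicator leaf panel (vein density, stomatal density,
    blade dimensions, cuticle and epidermis thicknesses and their ratios),
    coefficient-of-variation stability screening across seasons and regions,
    correlation screening against distribution zones, and four regression
    model families (multiple linear, composed multivariate nonlinear, and
    their principal-component counterparts) together with reduced variants
    that drop weakly correlated indicators. Ships the published fitted
    equations as reference predictors and a synthetic leaf-data generator
    with planted zone responses for parameter-recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
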