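Package: favmeta
Title: Favorability Models, Metapopulation Structure and Landscape
    Connectivity on Occurrence Grids
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits prevalence-corrected environmental favorability models to
    gridded presence/absence data (FDR-screened univariate logistic
    regression, forward-backward stepwise selection by AIC, significance
    trimming), evaluates them (CCR, sensitivity, specificity,
    under/over-prediction rates, Cohen's kappa, rank-based AUC,
    Hosmer-Lemeshow calibration), detects favorable habitat patches by
    connected-component labelling, classifies species distributions as
    metapopulations, and derives matrix connectivity from a friction
    surface by multi-source least-cost accumulation over a 16-cell
    knight's-move neighborhood.  A synthetic landscape generator with
    known generative parameters supports verification of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    withr
Config/testthat/edition: 3
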