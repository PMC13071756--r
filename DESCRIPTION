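Package: dispersalSDM
Title: Dispersal-Constrained Species Distribution Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds presence-background (MaxEnt-style) species
    distribution models from scratch, tunes feature classes and
    regularization by AICc, binarizes suitability at the TSS-optimal
    threshold, and projects species ranges annually to 2100 under an
    unlimited-dispersal counterfactual versus a dispersal-limited
    cellular colonization process driven by a truncated-exponential
    kernel. Includes occurrence cleaning and grid thinning, predictor
    selection by correlation and variance inflation, partial-ROC model
    evaluation, equal-area range accounting on the sphere, trajectory
    classification, and a virtual-species synthetic-data generator so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, graphics, tools, jsonlite,
    pracma, geosphere
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
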