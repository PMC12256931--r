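Package: bearcircuit
Title: Circuit-Theory Functional Connectivity for Bears Among Salmon Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to model functional connectivity for coastal grizzly and
    black bears moving among Pacific salmon spawning reaches. Builds an
    expert-parameterized cumulative resistance surface from terrain
    ruggedness, landcover, and open-water layers; solves the circuit-theory
    model (pairwise effective resistance, current-density maps) on the
    raster resistor network; converts cumulative current to a cost surface
    and ranks from-everywhere-to-everywhere least-cost corridors; and
    validates the resistance surface against bear transits inferred from
    genetic mark-recapture detections using Firth's penalized-likelihood
    logistic regression. A synthetic-landscape generator (terrain, landcover
    mosaic, island seascape, branching streams with species-labelled
    reaches, hair-snag sites, detection histories, transit outcomes) makes
    the whole pipeline testable without proprietary spatial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
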