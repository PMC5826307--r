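Package: crownarch
Title: Crown Structural Features and Tree Architecture Models from
    Airborne Laser Scanning
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Derives crown-internal and tree-external structural feature
    parameters from per-tree airborne laser scanning (ALS) point clouds,
    classifies tree species with an exhaustive feature-subset
    leave-one-out support vector machine, and identifies the Halle
    architecture model (Massart, Rauh, Roux or Attim) that best describes
    each classified species, attaching qualitative growth-habit knowledge
    and Gaussian divergence summaries.  A synthetic crown-archetype
    point-cloud simulator makes every pipeline stage testable without
    field data, and a command-line interface wires the stages into
    reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    grDevices,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
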