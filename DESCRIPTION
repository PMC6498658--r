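Package: discoursenet
Title: Discourse Network Analysis of Policy Debates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds actor congruence networks from coded stakeholder
    statements in media policy debates and analyses their coalition
    structure. Implements the subtract transformation with average
    activity normalisation and tie-weight thresholding, Girvan-Newman
    coalition detection, coalition-level network measures (size, degree
    centralisation, density, external ratio), a k = 2 clustering ensemble
    whose maximal modularity serves as a bipolarisation measure, sliding
    statement-window bipolarisation time series with LOESS smoothing, and
    a synthetic two-coalition debate generator with known ground truth
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    cluster,
    mclust,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
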