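Package: invaphylo
Title: Phylogenetic Relatedness and the Establishment of Non-Native Freshwater Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking the establishment of non-native
    freshwater fish species in river basins to their phylogenetic relatedness
    with resident native faunas. Classifies non-native occurrences into exotic
    and translocated species under country or biogeographical-realm scopes,
    computes nonnative-native mean and nearest-taxon phylogenetic distances
    (MPD, MNTD) together with native community diversity metrics, builds
    success/failure establishment records, fits binomial mixed models with
    species and basin-within-country random intercepts (marginal and
    conditional R-squared after Nakagawa and Schielzeth), and decomposes
    direct and indirect effects of native diversity through relatedness with
    a piecewise structural equation model. A synthetic-data generator with
    known ground truth (birth-death trees, Brownian trait evolution,
    environmental filtering, programmed establishment coefficients) makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    car,
    optparse,
    yaml
Config/testthat/edition: 3
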