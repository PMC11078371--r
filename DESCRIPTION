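Package: taxodive
Title: Taxonomic Distinctness, Beta Diversity and Spatial Structure of
    Presence/Absence Communities
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for taxonomic-distinctness analysis of presence/absence
    community data organised in a Linnaean hierarchy.  Computes average
    taxonomic distinctness and its variation with randomization confidence
    funnels, taxonomic beta diversity between samples, exponential distance
    decay of dissimilarity with bootstrap confidence intervals, Ward
    clustering with silhouette-based choice of the number of assemblages,
    ANOSIM permutation tests, distance-based Moran eigenvector maps,
    distance-based redundancy analysis, forward selection and variation
    partitioning.  Includes a synthetic community generator with known
    taxonomic, environmental and dispersal structure for end-to-end
    testing, plus CSV/JSON readers, a pipeline driver and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
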