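Package: panpronet
Title: Multiscale Protein Co-Expression Networks for Pan-Cancer Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential protein expression analysis and multiscale
    co-expression network modelling for multi-cohort tumor proteomics.
    Builds planar maximally filtered co-expression graphs per cohort,
    detects nested modules at tunable resolution, classifies module
    preservation across cohorts and against matched transcriptomes,
    merges cross-cohort preserved modules into pan-cancer protein
    interaction communities with core protein sets and a signed
    community cross-talk network, and ranks candidate key regulators by
    network-neighborhood enrichment of differential-expression
    signatures. Includes a synthetic multi-cohort panel generator with
    planted ground truth for end-to-end parameter-recovery testing, and
    an exact multi-set intersection test for recurrence analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    cluster,
    data.table,
    jsonlite,
    yaml,
    mclust,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
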