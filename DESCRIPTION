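Package: rootkin
Title: Kinematic and Multi-Omic Analysis of Root Growth-Zone Responses to
    Water Deficit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of cereal root growth
    maintenance under water deficit: kinematic growth-zone analysis
    (displacement-velocity reconstruction from cortical cell length
    profiles, logistic curve fitting, relative elongation rate, cell flux,
    radial-plus-tangential and volumetric expansion), water-relations and
    osmotic-adjustment arithmetic with a steady-state solute-deposition
    framework, metabolomic preprocessing and differential-abundance
    calling (Welch test, Benjamini-Hochberg FDR, fold-change gates),
    transcript threshold counting, topology-aware pathway impact analysis
    (hypergeometric enrichment with relative betweenness centrality), and
    a transcript-metabolite concordance classifier.  A seeded
    synthetic-data generator emulates the measurement designs these
    analyses assume, so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
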