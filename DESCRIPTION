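Package: hdmeanet
Title: Network Analysis of Developing Neuronal Cultures on High-Density
    Multielectrode Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the development of spontaneous network
    activity in dissociated cortical cultures recorded on high-density
    multielectrode arrays, and to contrast healthy maturation with an
    amyloid-beta(1-42) oligomer perturbation phenotype.  Implements
    per-electrode firing-rate and interspike-interval statistics,
    single-channel spike-burst and population network-burst detection,
    functional-connectivity inference from lagged cross-correlograms with
    spike-jitter surrogate significance, graph-theoretic summaries
    (clustering coefficient, characteristic path length, node degree,
    sender/receiver/broker node roles), and centre-of-activity trajectory
    analysis, together with a synthetic spike-raster generator that
    emulates the two culture phenotypes across days in vitro so that
    every analysis stage can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
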