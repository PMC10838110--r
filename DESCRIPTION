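Package: cavenet
Title: Subterranean Connectivity Networks and Conservation Priorities for
    Cave Communities
Version: 0.1.0
Authors@R: person("Cavenet", "Developers", role = c("aut", "cre"),
    email = "cavenet@example.org")
Description: Infers potential subterranean connectivity among caves from
    community similarity and builds weighted connectivity graphs to support
    conservation prioritization. Implements Bray-Curtis and taxonomic
    mean-pairwise-distance similarity with principal coordinate ordination,
    Moran's I correlograms with progressive Bonferroni correction,
    distance-based linear models (pseudo-F, permutation tests, forward
    selection by adjusted R squared), segmented (breakpoint) regression on
    pairwise predictor differences, potential-pairwise-connectivity graph
    construction with edge validation and weighting, edge-betweenness
    clustering, and a singularity index that flags priority caves together
    with their influence neighborhoods. A synthetic cave-system generator
    with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
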