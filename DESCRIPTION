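Package: carank
Title: Community-Aware Ranking of Influential Nodes in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreaders in networks with community
    structure. Instead of seeding a diffusion process with the globally
    top-ranked nodes of a centrality measure, the community-aware ranking
    scheme takes the best node of each community in turn, visiting
    communities from largest to smallest, so that selected spreaders are
    scattered across all dense regions of the graph. The package provides
    six classical centrality measures (degree, maximum neighborhood
    component, betweenness, closeness, Katz, PageRank), a discrete-time
    SIR epidemic simulator with the relative outbreak-size statistic used
    to compare ranking schemes, an LFR-style modular benchmark graph
    generator, plain-text graph/partition I/O, and an experiment runner
    that sweeps seeding budgets and aggregates gain curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
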