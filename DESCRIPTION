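Package: cprgame
Title: Common-Pool Resource Extraction Games on Bipartite Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and solver suite for common-pool resource (CPR)
    extraction games played on bipartite agent-resource networks. Generates
    network ensembles from degree-distribution specifications (configuration
    model with simple-graph enforcement), computes exact per-network Nash
    equilibria, Pareto efficient states, and reallocation steady states as
    concave potential / complementarity problems, integrates myopic
    quality-chasing reallocation dynamics that conserve each agent's total
    extraction effort, and solves the heterogeneous mean-field equations that
    predict degree-resolved extraction pressure, payoff shifts, collective
    wealth, and Gini-index changes from degree distributions alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
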