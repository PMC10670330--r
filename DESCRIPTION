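Package: linkclose
Title: Link Prediction with Weighted Local and Global Closeness
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Similarity-based link prediction for undirected, unweighted
    simple graphs. Implements the LGC and LGC* indices, which balance a
    local term (pair closeness plus clustering coefficient summed over
    common neighbours, degree-normalised) against a global term (pair
    closeness scaled by the network's average clustering coefficient and
    average shortest path length), together with eight classical baseline
    indices (common neighbours, Adamic-Adar, resource allocation,
    preferential attachment, Katz, local path, CN2D, CCLP). Provides an
    edge-holdout evaluation harness with AUC and precision-at-m metrics,
    repeated-trial experiments, lambda and training-ratio sweeps, synthetic
    graph generators for testing, plain-text edge-list input and output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
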