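Package: frailnet
Title: Network Frailness and Resilience via a Perturbed Master Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the frailness (inverse resilience) of an undirected
    network under simultaneous multi-node alterations. A master equation on
    the graph Laplacian of the column-normalized random walk is extended by
    an environment node coupled to the altered (query) nodes, and the
    perturbed stationary state is obtained both by a spectral iterative
    scheme and by a direct kernel solve. The frailness score is the
    Fiedler-scaled operator norm of the projected perturbation; its
    reciprocal is the critical coupling intensity at which the iterative
    scheme diverges, also retrievable by bisection. On top of the core model
    the package provides a cohort layer for binary gene-by-sample mutation
    matrices mapped onto protein-protein interaction subnetworks: per-sample
    frailness, gene-gene co-occurrence tables, a hypergeometric test for
    marginal (degree-one) mutations among the least resilient samples, and
    the two-component Gene Frailness Index. Seeded generators for synthetic
    networks and long-tailed mutation cohorts make every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
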