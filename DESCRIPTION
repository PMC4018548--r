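Package: spnet
Title: Statistical Parametric Networks and Density-Aware Topological Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the statistical analysis of multi-subject, multi-condition
    functional connectivity networks. Builds mean and differential statistical
    parametric networks (SPNs) from arrays of correlation matrices by
    mass-univariate edge and node inference with false discovery rate control;
    computes density-aware topological summaries (global efficiency, weighted
    efficiency, weighted density/cost, and density-integrated metrics that are
    invariant under monotone reweighting); and provides a modularity-versus-
    density simulation engine based on greedy modularity maximization over ring
    lattices, rewired lattices and uniform random graphs. A seeded synthetic-data
    generator with planted condition-dependent effects makes every analysis
    reproducible without imaging data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
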