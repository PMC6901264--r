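Package: netDrivers
Title: Personalized Cancer Driver Genes from Sample-Specific Network
    Rewiring and Structural Network Control
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds per-patient "state transition" networks from paired
    normal/tumor expression profiles by testing each edge of a reference
    gene-interaction network for a significant single-sample change in
    Pearson correlation (the paired sample-specific network statistic),
    then identifies a minimum set of personalized driver genes by exact
    nonlinear structural control of the resulting undirected network (a
    minimum node cover solved by branch and bound on a node-edge
    bipartite reformulation). Includes the single-sample network
    baselines (SSN, LIONESS), hub and differential-expression gene
    selectors, F-measure and hypergeometric enrichment evaluation,
    driver-frequency profiling, connected-component and power-law
    degree-exponent diagnostics, and seed-deterministic generators for
    scale-free and Erdos-Renyi graphs and planted-perturbation paired
    expression cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, igraph, jsonlite, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
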