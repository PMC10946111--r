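Package: pseudonet
Title: Covariate-Adjusted Differential Connectivity Analysis for Microbiome Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential network (connectivity) analysis for compositional
    microbiome count data with adjustment for clinical covariates. Taxon-taxon
    co-abundance networks are estimated per group with a deterministic SparCC
    basis-variance estimator, leave-one-out jackknife pseudo-values of degree
    centrality are computed per subject, and each taxon's pseudo-values are
    regressed on the group indicator plus covariates by least trimmed squares,
    with q-value control of the false discovery rate. Includes a synthetic-data
    generator (scale-free truth networks with group-specific perturbation and a
    zero-inflated log-normal Gaussian copula count model), a replicate
    benchmark with precision/recall/F1/accuracy scoring, file I/O for count
    and metadata tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    MASS,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
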