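Package: menet
Title: Molecular Ecological Network Analysis for Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and analysis of microbial co-occurrence networks from
    OTU abundance tables using random-matrix-theory (RMT) threshold selection.
    Implements the full pipeline: prevalence filtering, blank filling and log10
    transformation, Pearson similarity matrices, eigenvalue unfolding and
    nearest-neighbour spacing goodness-of-fit (Poisson vs. Wigner/GOE) for
    similarity-threshold selection, network topology panels (degree, density,
    clustering, path statistics, power-law fit, Krackhardt connectedness),
    greedy modularity module detection, within-/among-module connectivity
    (Zi-Pi) node-role classification, module eigengenes and their correlation
    with environmental variables, Mantel tests between community and
    environmental distances, and alpha-diversity estimators (Chao1, ACE,
    Shannon, Simpson) with rarefaction and NMDS ordination. Includes a
    synthetic-data generator with planted correlation modules so that every
    stage can be validated against a known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    vegan,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    xml2,
    withr
Config/testthat/edition: 3
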