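Package: scovnet
Title: Structural Covariance Network Analysis with Individual
    Differential Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and statistical comparison of structural
    covariance networks (SCNs) built from regional brain volumes, with a
    focus on thalamic nuclei. Provides group-level correlation networks
    with bipartite thalamo-(sub)cortical edge masking, threshold sweeps
    bounded by minimum wiring cost, strength-type graph measures with
    subject-level permutation tests and Benjamini-Hochberg FDR control,
    individual differential SCNs via template network perturbation with
    altered-edge calling and symptom-severity associations, hierarchical
    clustering of nuclei by covariance-difference profiles with
    Kelley-Gardner-Sutcliffe model selection and cophenetic comparison,
    multisite preprocessing (outlier screening, empirical-Bayes site
    harmonization, covariate residualization), and a synthetic multisite
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    ape,
    sva
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
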