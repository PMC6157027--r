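Package: methylVC
Title: Gene-Level Methylation Variance Components in Pedigree-Based Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models gene-proximal DNA-methylation covariance as an additional
    genetic variance component in a pedigree-based linear mixed model. Builds
    gene-specific unit-diagonal methylation relationship kernels from
    standardized CpG site values, computes expected kinship matrices from
    pedigrees, removes batch-like structure with principal components estimated
    on a random subset of sites, estimates per-site narrow-sense heritability,
    fits variance-component models by maximum likelihood, and screens genes
    with a likelihood-ratio test whose null is a 50:50 mixture of a point mass
    at zero and a 1-df chi-square. Includes a family-structured synthetic-data
    generator with known ground truth so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
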