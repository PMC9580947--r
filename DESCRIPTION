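Package: rvmsel
Title: Relevance Vector Machines for Genomic Prediction and Marker Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sparse Bayesian (relevance vector machine) regression for
    genomic selection in biparental crosses. Fits kernel RVMs (linear,
    polynomial, Gaussian) for phenotype prediction and linear basis RVMs
    whose relevance vectors are SNP markers, so that sparsity performs
    embedded marker selection. A bagged ensemble of basis RVMs ranks
    markers by how often they survive pruning, with signed
    (trait-increasing or trait-decreasing) mean effects. Includes repeated
    k-fold cross-validation with coefficient of determination, kernel
    model selection, a genotype/phenotype simulator with known causal
    structure, and TSV/BED readers and writers for marker tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
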