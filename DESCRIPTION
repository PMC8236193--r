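Package: mcpca
Title: Maximally Correlated PCA for Population Structure from
    Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonlinear dimension reduction for population-structure
    inference from low-coverage sequencing data.  Genotype dosages
    (posterior mean minor-allele counts) are discretized per SNP and
    per-SNP standardized transformations are optimized by block
    coordinate descent to maximize the Ky Fan q-norm (sum of the top q
    eigenvalues) of the transformed covariance matrix.  Includes readers
    for Beagle genotype-likelihood text and VCF GP/PL/DS fields,
    likelihood-to-dosage conversion with Hardy-Weinberg or uniform
    priors, equal-width, equal-frequency and Jenks natural-breaks
    discretization with Freedman-Diaconis bin counts, PCA and
    polynomial-kernel KPCA baselines with comparable explained-variance
    accounting, and a simulator for admixed multi-population genotypes
    observed at low coverage (Gamma read depths, Phred-quality driven
    genotype errors, read-level genotype likelihoods).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
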