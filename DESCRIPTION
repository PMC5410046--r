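Package: sprucegs
Title: Genomic Selection Analysis for Conifer Partial-Diallel Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for genomic selection in advanced-breeding
    conifer populations structured as interconnected full-sib families from a
    partial diallel mating design. Provides a gene-dropping simulator of such
    populations with known true breeding values, pedigree tools (numerator
    relationship matrix, relatedness classes), SNP genotype quality control and
    covariate coding, a pedigree-based individual-tree ("animal") mixed model
    and a ridge-regression marker model both solved by Gauss-Seidel iteration
    with residual update and extended by Gibbs sampling for variance
    components, family-stratified cross-validation with site, relatedness,
    marker-subset and training-size scenarios, and genetic-gain-per-unit-time
    calculators contrasting conventional and marker-based selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
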