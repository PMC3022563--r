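Package: episcan
Title: Exhaustive Two-Locus Epistasis Scans with Permutation-Based Error Control
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exhaustive detection of two-locus (SNP-pair) epistasis in
    genome-wide association studies. Implements three exact scan engines:
    an upper-bound-pruned two-locus ANOVA scan for quantitative traits over
    binary genotypes, a convex-bound scan for binary traits over binary
    genotypes (chi-square, G-test and mutual-information statistics), and a
    minimum-spanning-tree scan that incrementally maintains two-locus
    contingency tables for any genotype alphabet. All engines are exact:
    pruned scans return precisely the pairs a brute-force scan would return
    above a threshold. Error control is by phenotype permutation
    (family-wise error rate via the null distribution of the maximum pair
    statistic, and permutation-estimated false discovery rate for the
    all-pairs engine). Includes a synthetic genotype/phenotype simulator
    with planted epistatic effects, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
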