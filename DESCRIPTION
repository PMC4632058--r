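Package: ldknni
Title: LD-Informed k-Nearest Neighbour Genotype Imputation for Unordered
    Markers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Imputation of missing genotypes in unphased, biallelic,
    diploid SNP matrices such as those produced by genotyping-by-sequencing
    (GBS), without requiring a reference panel, a genetic map, or marker
    order.  Implements three imputation engines: per-SNP mode imputation,
    classical k-nearest-neighbour imputation (kNNi) using a missing-aware
    genome-wide taxicab distance and a distance-weighted modal vote, and
    LD-kNNi, in which the distance for each target SNP is computed only
    over the l SNPs in strongest linkage disequilibrium (squared Pearson
    correlation of dosages) with it.  Also provides parameter optimisation
    by masking known genotypes, the quality-control filters typical of GBS
    pipelines (missingness, minor allele frequency, exact Hardy-Weinberg
    heterozygote-excess test, clone pruning), a masking-based evaluation
    framework (genotype error, allele error, MAF-stratified error,
    allele-frequency bias, neighbour diagnostics), a block-LD genotype
    simulator with an analytic LD oracle, and readers/writers for VCF and
    plain tab-delimited dosage matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
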