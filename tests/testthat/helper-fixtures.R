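# Small in-code fixtures shared across test files.

# geno_matrix from a plain matrix, letting NA stand for missing
gm_of <- function(m, ...) geno_matrix(m, ...)

# random dosage matrix with MCAR missingness; genotypes drawn per SNP from
# a rough Hardy-Weinberg spectrum so all three codes occur
random_gm <- function(n_samples, n_snps, miss = 0.1, seed = 1) {
  withr::with_seed(seed, {
    f <- runif(n_snps, 0.1, 0.5)
    d <- vapply(f, function(q) rbinom(n_samples, 2L, q), integer(n_samples))
    if (n_samples == 1L) d <- matrix(d, nrow = 1L)
    d[matrix(runif(length(d)) < miss, nrow(d))] <- NA_integer_
    geno_matrix(d)
  })
}

# minimal VCF text for the reader tests
write_test_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
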