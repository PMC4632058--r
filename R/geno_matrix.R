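# Missing genotypes are NA_integer_ in memory; the on-disk numeric dialect
# uses -1 (see read_dosage/write_dosage).

#' Construct a genotype matrix
#'
#' The central container of the package: an unphased, biallelic, diploid
#' genotype matrix coded as allele dosages. Rows are samples, columns are
#' SNPs. Each entry is 0 (homozygous for one allele, conventionally the
#' major allele), 1 (heterozygous), 2 (homozygous for the other allele,
#' conventionally the minor allele), or `NA` (missing call).
#'
#' No marker order is assumed anywhere in the package: chromosome and
#' position, when present, are carried as opaque labels for bookkeeping and
#' diagnostics only.
#'
#' @param dosage integer (or coercible) matrix of 0/1/2/`NA`, samples in
#'   rows, SNPs in columns.
#' @param samples character vector of unique sample IDs (default: rownames,
#'   else `S1..Sn`).
#' @param snps character vector of unique SNP IDs (default: colnames, else
#'   `snp1..snpm`).
#' @param chrom optional per-SNP chromosome label (length = number of SNPs).
#' @param pos optional per-SNP 1-based position. `chrom` and `pos` must be
#'   given together or not at all.
#' @return an object of class `geno_matrix`: a list with elements `dosage`
#'   (integer matrix with dimnames), `chrom`, `pos`.
#' @examples
#' gm <- geno_matrix(rbind(a = c(0, 1, 2), b = c(1, NA, 0)))
#' gm
#' @export
geno_matrix <- function(dosage, samples = rownames(dosage),
                        snps = colnames(dosage), chrom = NULL, pos = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage %d at (sample %d, snp %d): must be 0, 1, 2 or NA",
                 dosage[bad][1L], idx[1L], idx[2L]))
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(dosage)))
  samples <- as.character(samples)
  snps <- as.character(snps)
  if (length(samples) != nrow(dosage)) stop("length(samples) != nrow(dosage)")
  if (length(snps) != ncol(dosage)) stop("length(snps) != ncol(dosage)")
  if (anyDuplicated(samples)) stop("duplicated sample IDs: ",
                                   paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(snps)) stop("duplicated SNP IDs: ",
                                paste(unique(snps[duplicated(snps)]), collapse = ", "))
  if (xor(is.null(chrom), is.null(pos)))
    stop("chrom and pos must be supplied together or not at all")
  if (!is.null(chrom)) {
    if (length(chrom) != ncol(dosage) || length(pos) != ncol(dosage))
      stop("chrom/pos must have one entry per SNP")
    chrom <- as.character(chrom)
    pos <- as.integer(pos)
  }
  dimnames(dosage) <- list(samples, snps)
  structure(list(dosage = dosage, chrom = chrom, pos = pos),
            class = "geno_matrix")
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / SNPs in a genotype matrix
#' @param gm a [geno_matrix].
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(gm) ncol(gm$dosage)

#' Sample and SNP identifiers
#' @param gm a [geno_matrix].
#' @return character vector of IDs.
#' @export
sample_ids <- function(gm) rownames(gm$dosage)

#' @rdname sample_ids
#' @export
snp_ids <- function(gm) colnames(gm$dosage)

#' Fraction of missing genotype calls
#' @param gm a [geno_matrix].
#' @return fraction in \[0, 1\].
#' @export
missing_rate <- function(gm) mean(is.na(gm$dosage))

#' Subset a genotype matrix
#'
#' Standard `[i, j]` subsetting; chromosome/position labels follow the SNP
#' subset. Always returns a `geno_matrix` (no dropping to vector).
#'
#' @param x a [geno_matrix].
#' @param i sample (row) index.
#' @param j SNP (column) index.
#' @param ... ignored.
#' @return a [geno_matrix].
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, colnames(x$dosage))
  if (is.logical(j)) j <- which(j)
  geno_matrix(x$dosage[i, j, drop = FALSE],
              chrom = if (!is.null(x$chrom)) x$chrom[j],
              pos = if (!is.null(x$pos)) x$pos[j])
}

#' @export
as.matrix.geno_matrix <- function(x, ...) x$dosage

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs, %.1f%% missing%s\n",
              nrow(x$dosage), ncol(x$dosage), 100 * mean(is.na(x$dosage)),
              if (is.null(x$chrom)) "" else
                sprintf(", %d chromosome(s)", length(unique(x$chrom)))))
  ns <- min(5L, nrow(x$dosage))
  ms <- min(8L, ncol(x$dosage))
  print(x$dosage[seq_len(ns), seq_len(ms), drop = FALSE])
  if (nrow(x$dosage) > ns || ncol(x$dosage) > ms) cat("...\n")
  invisible(x)
}

#' Recode each SNP so that dosage counts the minor allele
#'
#' For every SNP whose coded-allele frequency among non-missing calls
#' exceeds 0.5, dosages are flipped (`d -> 2 - d`) so that afterwards every
#' SNP has minor-allele frequency at most 0.5. A frequency of exactly 0.5
#' is left unflipped (deterministic, order-independent tie rule). All
#' imputation distances in this package use absolute dosage differences and
#' are therefore invariant to this recoding; it matters only for reporting
#' (e.g. MAF spectra).
#'
#' @param gm a [geno_matrix].
#' @return a [geno_matrix] with attribute `flipped`: a named logical vector
#'   (one per SNP) recording which columns were flipped, so results can be
#'   mapped back to the original coding.
#' @export
recode_to_minor <- function(gm) {
  f <- coded_allele_freq(gm)
  flip <- !is.na(f) & f > 0.5
  d <- gm$dosage
  d[, flip] <- 2L - d[, flip, drop = FALSE]
  out <- geno_matrix(d, chrom = gm$chrom, pos = gm$pos)
  names(flip) <- colnames(d)
  attr(out, "flipped") <- flip
  out
}

#' Per-SNP allele frequencies
#'
#' `coded_allele_freq` returns the frequency f of the allele counted by the
#' dosage coding, `sum(dosage) / (2 * n_nonmissing)` per SNP.
#' `snp_maf` returns the minor allele frequency `min(f, 1 - f)`.
#' SNPs with no non-missing calls give `NA`.
#'
#' @param gm a [geno_matrix].
#' @return named numeric vector, one entry per SNP.
#' @export
coded_allele_freq <- function(gm) {
  n <- colSums(!is.na(gm$dosage))
  f <- colSums(gm$dosage, na.rm = TRUE) / (2 * n)
  f[n == 0L] <- NA_real_
  f
}

#' @rdname coded_allele_freq
#' @export
snp_maf <- function(gm) {
  f <- coded_allele_freq(gm)
  pmin(f, 1 - f)
}
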