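# File formats: VCF 4.x (GT field only) via vcfR, and the plain
# tab-delimited dosage dialect (0/1/2, -1 = missing) used by many GBS
# imputation tools.

#' Read a genotype matrix from a VCF file
#'
#' Only the GT field is consumed. Diploid calls are converted to dosages:
#' `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2`, `./. -> NA`. Phased
#' separators (`|`) are accepted and treated as unphased. Dosage counts the
#' ALT allele as coded in the file; use [recode_to_minor()] if minor-allele
#' coding is wanted.
#'
#' @param path path to a VCF (optionally bgzipped) file.
#' @param skip_nonbiallelic if `TRUE` (default), sites with more than two
#'   alleles or with non-SNP (indel) alleles are skipped and their count
#'   reported as a message; if `FALSE` such sites are an error.
#' @return a [geno_matrix] with chromosome and position labels.
#' @export
read_vcf <- function(path, skip_nonbiallelic = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic_snp)) {
    if (!skip_nonbiallelic)
      stop(sprintf("%d non-biallelic or non-SNP record(s); first at %s:%s",
                   sum(!biallelic_snp),
                   fix[!biallelic_snp, "CHROM"][1L], fix[!biallelic_snp, "POS"][1L]))
    message(sprintf("read_vcf: skipped %d non-biallelic/non-SNP record(s)",
                    sum(!biallelic_snp)))
  }
  keep <- which(biallelic_snp)
  if (length(keep) == 0L) stop("no biallelic SNP records left in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt_clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = nrow(gt_clean), ncol = ncol(gt_clean))
  dos[gt_clean %in% c("0/0")] <- 0L
  dos[gt_clean %in% c("0/1", "1/0")] <- 1L
  dos[gt_clean %in% c("1/1")] <- 2L
  unknown <- !is.na(gt_clean) & is.na(dos) & !(gt_clean %in% c("./.", ".", "./0", "0/."))
  if (any(unknown)) {
    idx <- which(unknown, arr.ind = TRUE)[1L, ]
    bad <- gt_clean[unknown][1L]
    if (!grepl("^[0-9.]+/[0-9.]+$", bad))
      stop(sprintf("sample '%s' has non-diploid GT '%s' at record %d",
                   colnames(gt_clean)[idx[2L]], gt[unknown][1L], idx[1L]))
    stop(sprintf("unsupported GT '%s' for sample '%s' at record %d",
                 gt[unknown][1L], colnames(gt_clean)[idx[2L]], idx[1L]))
  }
  ids <- fix[keep, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[keep, "CHROM"][noid], "_", fix[keep, "POS"][noid])
  geno_matrix(t(dos), samples = colnames(gt_clean), snps = ids,
              chrom = fix[keep, "CHROM"], pos = as.integer(fix[keep, "POS"]))
}

#' Write a genotype matrix to a VCF file
#'
#' Emits a minimal VCF 4.2 with GT-only genotype columns; missing calls
#' become `./.`. Because dosages carry no nucleotide information, REF/ALT
#' are written as placeholder alleles `A`/`C`. When the matrix has no
#' chromosome/position labels, a placeholder contig `0` with positions
#' `1..n` is written and flagged in the header. Output is byte-stable for a
#' fixed input.
#'
#' @param gm a [geno_matrix].
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  placeholder <- is.null(gm$chrom)
  chrom <- if (placeholder) rep("0", n_snps(gm)) else gm$chrom
  pos <- if (placeholder) seq_len(n_snps(gm)) else gm$pos
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=ldknni_%s", as.character(utils::packageVersion("ldknni"))),
           if (placeholder)
             "##ldknni_placeholder_coordinates=contig 0, positions 1..n (input had no chrom/pos)",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_ids(gm)), collapse = "\t"))
  gt_code <- c("0/0", "0/1", "1/1")
  body <- character(n_snps(gm))
  for (j in seq_len(n_snps(gm))) {
    d <- gm$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    body[j] <- paste(c(chrom[j], pos[j], snp_ids(gm)[j], "A", "C", ".",
                       ".", ".", "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a genotype matrix from a tab-delimited dosage file
#'
#' The dialect is one row per sample, tab-separated integer dosages with
#' `-1` for missing. An optional header row of SNP IDs and an optional
#' first column of sample IDs are auto-detected (any token that is not an
#' integer in `{-1, 0, 1, 2}` marks the row/column as labels). Lines
#' starting with `#` are ignored.
#'
#' @param path input file path.
#' @return a [geno_matrix] (no chromosome/position labels).
#' @export
read_dosage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty dosage file: ", path)
  tok <- strsplit(lines, "\t", fixed = TRUE)
  is_code <- function(x) grepl("^(-1|0|1|2)$", x)
  has_header <- !all(is_code(tok[[1L]][-1L])) && length(tok) > 1L
  # header detection: a first line whose non-leading tokens are not all codes
  if (!all(is_code(tok[[1L]])) && all(is_code(tok[[1L]][-1L])) && length(tok) > 1L) {
    # only the first token is non-numeric: could be a header corner or a
    # sample id; treat as data row with sample-id column (no header)
    has_header <- FALSE
  }
  snps <- NULL
  if (has_header) {
    snps <- tok[[1L]]
    tok <- tok[-1L]
  }
  if (length(tok) == 0L) stop("dosage file has a header but no data rows: ", path)
  has_ids <- !all(vapply(tok, function(x) is_code(x[1L]), logical(1)))
  samples <- NULL
  if (has_ids) {
    samples <- vapply(tok, `[`, character(1), 1L)
    tok <- lapply(tok, `[`, -1L)
    if (!is.null(snps) && length(snps) == length(tok[[1L]]) + 1L)
      snps <- snps[-1L]  # header had a corner label above the id column
  }
  width <- length(tok[[1L]])
  for (i in seq_along(tok)) {
    if (length(tok[[i]]) != width)
      stop(sprintf("ragged dosage file: row %d has %d fields, expected %d",
                   i + has_header, length(tok[[i]]) + has_ids, width + has_ids))
    bad <- which(!is_code(tok[[i]]))
    if (length(bad))
      stop(sprintf("invalid dosage token '%s' at row %d, column %d (allowed: -1, 0, 1, 2)",
                   tok[[i]][bad[1L]], i + has_header, bad[1L] + has_ids))
  }
  d <- matrix(as.integer(unlist(tok)), nrow = length(tok), byrow = TRUE)
  d[d == -1L] <- NA_integer_
  geno_matrix(d, samples = samples, snps = snps)
}

#' Write a genotype matrix to a tab-delimited dosage file
#'
#' Inverse of [read_dosage()]: writes a provenance comment line, a header
#' row of SNP IDs (corner label `sample`), then one row per sample with
#' `-1` for missing calls.
#'
#' @param gm a [geno_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(gm, path) {
  d <- gm$dosage
  d[is.na(d)] <- -1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ldknni %s dosage matrix: %d samples x %d SNPs (-1 = missing)",
                     as.character(utils::packageVersion("ldknni")),
                     nrow(d), ncol(d)), con)
  writeLines(paste(c("sample", colnames(d)), collapse = "\t"), con)
  writeLines(paste(rownames(d), apply(d, 1L, paste, collapse = "\t"), sep = "\t"),
             con)
  invisible(path)
}

#' Read/write a genotype matrix, picking the format from the file extension
#'
#' `.vcf` / `.vcf.gz` dispatch to [read_vcf()] / [write_vcf()]; anything
#' else is treated as the tab-delimited dosage dialect.
#'
#' @param path file path.
#' @param gm a [geno_matrix] (for writing).
#' @param ... passed to the format-specific reader/writer.
#' @return a [geno_matrix] (reading) or `path` invisibly (writing).
#' @export
read_genotypes <- function(path, ...) {
  if (grepl("\\.vcf(\\.gz)?$", path)) read_vcf(path, ...) else read_dosage(path)
}

#' @rdname read_genotypes
#' @export
write_genotypes <- function(gm, path, ...) {
  if (grepl("\\.vcf(\\.gz)?$", path)) write_vcf(gm, path) else write_dosage(gm, path)
}
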