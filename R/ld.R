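# Linkage disequilibrium between unordered, unphased markers, measured as
# the squared Pearson correlation (r^2) of 0/1/2 dosages over
# pairwise-complete samples -- the standard phase-free composite-LD
# surrogate. Everything here is missing-aware and built from dense matrix
# cross-products so that matrices with thousands of SNPs remain fast.

# 0/1 indicator matrices per dosage class plus the observed mask, with
# missing entries contributing 0 everywhere. The workhorse representation
# for all pairwise quantities.
.dosage_indicators <- function(G) {
  M <- !is.na(G)
  out <- list(M = matrix(as.numeric(M), nrow(G)))
  for (a in 0:2) {
    I <- G == a
    I[!M] <- FALSE
    out[[paste0("I", a)]] <- matrix(as.numeric(I), nrow(G))
  }
  out
}

#' Pairwise squared-correlation LD matrix
#'
#' Computes r^2 between every pair of SNPs as the squared Pearson
#' correlation of dosage vectors over samples where both SNPs are
#' non-missing (pairwise-complete deletion). Pairs with fewer than
#' `min_overlap` shared samples, or with zero dosage variance on the
#' overlap, get r^2 = 0. The diagonal is `NA` (a SNP is never its own LD
#' partner).
#'
#' @param gm a [geno_matrix].
#' @param min_overlap minimum pairwise-complete sample count for a defined
#'   correlation (default 2).
#' @return symmetric SNPs-by-SNPs numeric matrix with values in \[0, 1\]
#'   and `NA` on the diagonal.
#' @export
ld_r2_matrix <- function(gm, min_overlap = 2L) {
  G <- gm$dosage
  M <- matrix(as.numeric(!is.na(G)), nrow(G))
  X <- G
  X[is.na(X)] <- 0L
  X <- matrix(as.numeric(X), nrow(G))
  X2 <- X * X
  N <- crossprod(M)                 # pairwise-complete counts
  Sx <- crossprod(X, M)             # sum of x over samples where partner observed
  Sxy <- crossprod(X)
  Sxx <- crossprod(X2, M)
  num <- N * Sxy - Sx * t(Sx)
  vx <- N * Sxx - Sx^2
  den <- vx * t(vx)
  r2 <- matrix(0, nrow(N), ncol(N))
  ok <- den > 0 & N >= min_overlap
  r2[ok] <- num[ok]^2 / den[ok]
  r2[r2 > 1] <- 1                   # guard against rounding drift
  diag(r2) <- NA_real_
  dimnames(r2) <- list(snp_ids(gm), snp_ids(gm))
  r2
}

#' LD between one pair of SNPs
#'
#' Scalar convenience wrapper: squared Pearson correlation of the two
#' SNPs' dosage vectors over pairwise-complete samples, with the same
#' degenerate-case convention as [ld_r2_matrix()] (overlap below
#' `min_overlap` or zero variance gives 0).
#'
#' @param gm a [geno_matrix].
#' @param i,j SNP indices (or IDs), `i != j`.
#' @param min_overlap minimum pairwise-complete sample count (default 2).
#' @return r^2 in \[0, 1\].
#' @export
pairwise_r2 <- function(gm, i, j, min_overlap = 2L) {
  if (is.character(i)) i <- match(i, snp_ids(gm))
  if (is.character(j)) j <- match(j, snp_ids(gm))
  stopifnot(i != j)
  x <- gm$dosage[, i]
  y <- gm$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(0)
  x <- x[ok]
  y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  min(stats::cor(x, y)^2, 1)
}

#' Build the per-SNP list of strongest-LD partners
#'
#' For every SNP, ranks all other SNPs by r^2 ([ld_r2_matrix()]) and keeps
#' the top `l`, sorted by decreasing r^2 with ties broken by ascending SNP
#' index (deterministic). This index is what restricts the LD-kNNi
#' distance; it is computed once per (matrix, l) and reused across all
#' imputations.
#'
#' @param gm a [geno_matrix].
#' @param l number of LD partners to retain per SNP.
#' @param min_overlap passed to [ld_r2_matrix()].
#' @param r2 optionally, a precomputed matrix from [ld_r2_matrix()] (used
#'   by the tuner to share one LD computation across many `l` values).
#' @return an object of class `ld_index`: list with `l`, `min_overlap`,
#'   `neighbors` (per-SNP integer vector of partner indices) and `r2`
#'   (per-SNP numeric vector of their r^2 values).
#' @export
build_ld_index <- function(gm, l, min_overlap = 2L, r2 = NULL) {
  stopifnot(l >= 1)
  if (is.null(r2)) r2 <- ld_r2_matrix(gm, min_overlap)
  m <- ncol(r2)
  neighbors <- vector("list", m)
  r2vals <- vector("list", m)
  l_eff <- min(l, m - 1L)
  for (p in seq_len(m)) {
    # rank on rounded values so that mathematically tied r2 computed in a
    # different summation order still breaks ties by SNP index
    v <- round(r2[, p], 12L)
    v[p] <- -Inf                       # never self
    ord <- order(-v, seq_len(m))[seq_len(l_eff)]
    neighbors[[p]] <- ord
    r2vals[[p]] <- r2[ord, p]
  }
  structure(list(l = as.integer(l), min_overlap = as.integer(min_overlap),
                 neighbors = neighbors, r2 = r2vals,
                 snp_ids = colnames(r2)),
            class = "ld_index")
}

#' @export
print.ld_index <- function(x, ...) {
  cat(sprintf("ld_index: %d SNPs, l = %d (min_overlap = %d)\n",
              length(x$neighbors), x$l, x$min_overlap))
  invisible(x)
}

#' Write an LD index as a tab-delimited diagnostic table
#'
#' One row per (SNP, rank): `snp_id`, `rank`, `neighbor_snp_id`, `r2`.
#'
#' @param index an `ld_index` from [build_ld_index()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_index <- function(index, path) {
  ids <- index$snp_ids
  rows <- unlist(lapply(seq_along(index$neighbors), function(p) {
    nb <- index$neighbors[[p]]
    if (length(nb) == 0L) return(character(0))
    sprintf("%s\t%d\t%s\t%.6g", ids[p], seq_along(nb), ids[nb], index$r2[[p]])
  }))
  writeLines(c("snp_id\trank\tneighbor_snp_id\tr2", rows), path)
  invisible(path)
}

# Genome-wide pairwise sample distances (missing-aware taxicab).
# Returns the normalized distance matrix d (sum |g_i - g_j| / n_overlap,
# NaN where n_overlap = 0) and the overlap-count matrix n. The |a - b|
# kernel over codes {0,1,2} decomposes into indicator cross-products, so
# the whole matrix costs a handful of BLAS calls.
pairwise_sample_distance <- function(gm) {
  ind <- .dosage_indicators(gm$dosage)
  numer <- tcrossprod(ind$I0, ind$I1 + 2 * ind$I2) +
    tcrossprod(ind$I1, ind$I0 + ind$I2) +
    tcrossprod(ind$I2, 2 * ind$I0 + ind$I1)
  n <- tcrossprod(ind$M)
  list(d = numer / n, n = n)
}
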