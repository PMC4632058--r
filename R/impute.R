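# The three imputation engines. All of them predict each missing entry
# from the ORIGINAL observed data only -- imputed values are never fed back
# into distances or votes, so results are independent of imputation order.
#
# Tie rules (all deterministic, flagged in the documentation):
#   * equal-distance neighbours -> ascending sample index
#   * equal vote scores        -> smallest genotype code
#   * zero-distance neighbours (kNNi only; LD-kNNi distances are >= c > 0)
#     -> unweighted mode over the zero-distance members

#' Missing-aware taxicab distance between two samples
#'
#' The mean absolute dosage difference over SNPs where both samples are
#' non-missing: `sum(|g1 - g2|) / n`, with `n` the number of SNPs actually
#' summed. Restricting to a subset of SNPs gives the building block of the
#' LD-restricted distance.
#'
#' @param gm a [geno_matrix].
#' @param s1,s2 sample indices (or IDs), `s1 != s2`.
#' @param snp_subset optional integer vector of SNP indices to sum over
#'   (default: all SNPs).
#' @return list with `distance` (NaN when no SNP overlaps) and `n_used`.
#' @export
taxicab_distance <- function(gm, s1, s2, snp_subset = NULL) {
  if (is.character(s1)) s1 <- match(s1, sample_ids(gm))
  if (is.character(s2)) s2 <- match(s2, sample_ids(gm))
  stopifnot(s1 != s2)
  x <- gm$dosage[s1, ]
  y <- gm$dosage[s2, ]
  if (!is.null(snp_subset)) {
    x <- x[snp_subset]
    y <- y[snp_subset]
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  list(distance = if (n == 0L) NaN else sum(abs(x[ok] - y[ok])) / n,
       n_used = n)
}

#' Distance-weighted modal vote over a neighbour set
#'
#' Returns the genotype class `a` in `{0, 1, 2}` maximizing
#' `sum(1/d_i)` over neighbours carrying `a`. If any neighbour is at
#' distance exactly 0 (possible for the genome-wide distance), the vote is
#' restricted to the zero-distance neighbours and their unweighted mode is
#' returned. Score ties go to the smallest genotype code.
#'
#' @param genotypes integer vector of neighbour genotypes at the target SNP
#'   (no missing values).
#' @param distances numeric vector of neighbour distances (same length,
#'   all `>= 0`).
#' @return imputed genotype in `{0, 1, 2}`.
#' @export
weighted_mode <- function(genotypes, distances) {
  stopifnot(length(genotypes) == length(distances), length(genotypes) >= 1L)
  zero <- distances == 0
  if (any(zero)) {
    g <- genotypes[zero]
    scores <- tabulate(g + 1L, nbins = 3L)
  } else {
    w <- 1 / distances
    scores <- vapply(0:2, function(a) sum(w[genotypes == a]), numeric(1))
  }
  which.max(scores) - 1L   # first max -> smallest code on ties
}

# Per-SNP modal genotype over non-missing calls, ties to the smaller code.
# Errors on fully missing columns (no defined mode).
.column_modes <- function(G) {
  counts <- vapply(0:2, function(a) colSums(G == a, na.rm = TRUE),
                   numeric(ncol(G)))
  if (ncol(G) == 1L) counts <- matrix(counts, nrow = 1L)
  empty <- rowSums(counts) == 0
  if (any(empty))
    stop("SNP(s) with no observed genotypes cannot be imputed: ",
         paste(utils::head(colnames(G)[empty], 5L), collapse = ", "))
  max.col(counts, ties.method = "first") - 1L
}

# ---------------------------------------------------------------------------
# Coordinate-level prediction workhorses. `coords` is a 2-column integer
# matrix of (sample, snp) positions to predict; predictions use only the
# observed entries of `gm`. These are shared by the full-matrix imputers
# and by the evaluation/tuning code (which only needs masked coordinates).

.predict_mode_at <- function(gm, coords) {
  modes <- .column_modes(gm$dosage)
  modes[coords[, 2L]]
}

.predict_knni_at <- function(gm, coords, k, dist = NULL) {
  stopifnot(k >= 1)
  G <- gm$dosage
  if (is.null(dist)) dist <- pairwise_sample_distance(gm)
  D <- dist$d
  D[dist$n == 0L] <- NA_real_        # undefined distance -> ineligible
  diag(D) <- NA_real_
  modes <- .column_modes(G)
  obs <- !is.na(G)
  out <- integer(nrow(coords))
  for (p in unique(coords[, 2L])) {
    rows <- which(coords[, 2L] == p)
    cand_all <- which(obs[, p])
    for (r in rows) {
      s <- coords[r, 1L]
      cand <- cand_all[cand_all != s]
      d <- D[s, cand]
      keep <- !is.na(d)
      cand <- cand[keep]
      d <- d[keep]
      if (length(cand) == 0L) {       # no eligible neighbour: column mode
        out[r] <- modes[p]
        next
      }
      sel <- order(d, cand)[seq_len(min(k, length(cand)))]
      out[r] <- weighted_mode(G[cand[sel], p], d[sel])
    }
  }
  out
}

.predict_ldknni_at <- function(gm, coords, k, l, c = 1, index = NULL) {
  stopifnot(k >= 1, l >= 1, c > 0)
  G <- gm$dosage
  if (is.null(index)) index <- build_ld_index(gm, l)
  modes <- .column_modes(G)
  obs <- !is.na(G)
  ind <- .dosage_indicators(G)
  # per-class weights for the |a-b| kernel: row block A against all samples
  out <- integer(nrow(coords))
  n_samp <- nrow(G)
  for (p in unique(coords[, 2L])) {
    rows <- which(coords[, 2L] == p)
    S <- coords[rows, 1L]
    Lp <- index$neighbors[[p]]
    if (length(Lp) > l) Lp <- Lp[seq_len(l)]
    cand_all <- which(obs[, p])
    if (length(Lp) == 0L) {
      Dl <- matrix(c, length(S), n_samp)
    } else {
      IA0 <- ind$I0[S, Lp, drop = FALSE]
      IA1 <- ind$I1[S, Lp, drop = FALSE]
      IA2 <- ind$I2[S, Lp, drop = FALSE]
      MA <- ind$M[S, Lp, drop = FALSE]
      IB0 <- ind$I0[, Lp, drop = FALSE]
      IB1 <- ind$I1[, Lp, drop = FALSE]
      IB2 <- ind$I2[, Lp, drop = FALSE]
      MB <- ind$M[, Lp, drop = FALSE]
      numer <- tcrossprod(IA0, IB1 + 2 * IB2) +
        tcrossprod(IA1, IB0 + IB2) +
        tcrossprod(IA2, 2 * IB0 + IB1)
      n_ovl <- tcrossprod(MA, MB)
      Dl <- c + numer / n_ovl
      Dl[n_ovl == 0] <- c            # no shared LD SNP: distance is just c
    }
    for (ii in seq_along(rows)) {
      s <- S[ii]
      cand <- cand_all[cand_all != s]
      if (length(cand) == 0L) {
        out[rows[ii]] <- modes[p]
        next
      }
      d <- Dl[ii, cand]
      sel <- order(d, cand)[seq_len(min(k, length(cand)))]
      out[rows[ii]] <- weighted_mode(G[cand[sel], p], d[sel])
    }
  }
  out
}

.fill <- function(gm, coords, values) {
  d <- gm$dosage
  d[coords] <- as.integer(values)
  geno_matrix(d, chrom = gm$chrom, pos = gm$pos)
}

.missing_coords <- function(gm) {
  which(is.na(gm$dosage), arr.ind = TRUE, useNames = FALSE)
}

# ---------------------------------------------------------------------------

#' Impute missing genotypes with the per-SNP mode
#'
#' Every missing entry is replaced by the most frequent non-missing
#' genotype in its SNP column (ties to the smaller code). The simplest
#' baseline: ignores all between-sample information.
#'
#' @param gm a [geno_matrix]; every SNP must have at least one observed
#'   call.
#' @return a complete [geno_matrix]; observed entries are untouched.
#' @export
impute_mode <- function(gm) {
  coords <- .missing_coords(gm)
  if (nrow(coords) == 0L) return(gm)
  .fill(gm, coords, .predict_mode_at(gm, coords))
}

#' Impute missing genotypes by k nearest neighbours (kNNi)
#'
#' For each missing entry (sample s, SNP p): the genome-wide taxicab
#' distance ([taxicab_distance()]) from s to every other sample is
#' computed; samples missing at p, or sharing no observed SNP with s, are
#' ineligible; the k nearest eligible samples (distance ties by ascending
#' sample index) vote via [weighted_mode()]. If no sample is eligible the
#' column mode is used. All distances come from the original matrix; no
#' chaining of imputed values.
#'
#' @param gm a [geno_matrix].
#' @param k neighbour count (default 8, a good genome-wide-distance
#'   default for diverse GBS panels).
#' @return a complete [geno_matrix].
#' @export
impute_knni <- function(gm, k = 8) {
  coords <- .missing_coords(gm)
  if (nrow(coords) == 0L) return(gm)
  .fill(gm, coords, .predict_knni_at(gm, coords, k))
}

#' Impute missing genotypes by LD-restricted k nearest neighbours (LD-kNNi)
#'
#' As [impute_knni()], except that the distance used for a missing entry at
#' SNP p is computed only over the `l` SNPs in strongest LD with p (from
#' [build_ld_index()]) and a constant `c` is added:
#' `d = c + sum(|g1 - g2|) / n` over the LD partners where both samples are
#' observed (`n` of them; when `n = 0` the distance is `c` alone and the
#' pair stays eligible). The constant keeps every distance positive, so the
#' inverse-distance vote is always defined. Neighbours are chosen per
#' target SNP, so two entries of the same sample generally use different
#' neighbours.
#'
#' @param gm a [geno_matrix].
#' @param k neighbour count (default 5).
#' @param l number of LD partners per SNP (default 20).
#' @param c additive distance constant (default 1; must be > 0).
#' @param index optional precomputed [build_ld_index()] result for `gm`
#'   (with `l` at least as large as requested).
#' @return a complete [geno_matrix].
#' @export
impute_ldknni <- function(gm, k = 5, l = 20, c = 1, index = NULL) {
  coords <- .missing_coords(gm)
  if (nrow(coords) == 0L) return(gm)
  .fill(gm, coords, .predict_ldknni_at(gm, coords, k, l, c, index))
}

#' Impute with a named method
#'
#' Dispatch helper used by the tuner, the evaluator and the command line:
#' `method` is one of `"mode"`, `"knni"`, `"ldknni"`.
#'
#' @param gm a [geno_matrix].
#' @param method imputation engine name.
#' @param k,l,c engine parameters (unused ones ignored); `NULL` picks the
#'   engine's default (k = 8 for knni, k = 5 and l = 20 for ldknni).
#' @return a complete [geno_matrix].
#' @export
impute_genotypes <- function(gm, method = c("ldknni", "knni", "mode"),
                             k = NULL, l = NULL, c = 1) {
  method <- match.arg(method)
  switch(method,
         mode = impute_mode(gm),
         knni = impute_knni(gm, k = if (is.null(k)) 8 else k),
         ldknni = impute_ldknni(gm, k = if (is.null(k)) 5 else k,
                                l = if (is.null(l)) 20 else l, c = c))
}

# Internal dispatcher at coordinate level (evaluation/tuning).
.predict_at <- function(gm, coords, method, k = NULL, l = NULL, c = 1,
                        index = NULL, dist = NULL) {
  switch(method,
         mode = .predict_mode_at(gm, coords),
         knni = .predict_knni_at(gm, coords, k = if (is.null(k)) 8 else k,
                                 dist = dist),
         ldknni = .predict_ldknni_at(gm, coords,
                                     k = if (is.null(k)) 5 else k,
                                     l = if (is.null(l)) 20 else l,
                                     c = c, index = index),
         stop("unknown method: ", method))
}
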