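# Masking-based evaluation: hide known genotypes, impute them, and score
# the predictions. Genotype error counts wrong calls; allele error counts
# wrong alleles (each diploid call contributes 2), so a het called as a
# homozygote costs one allele, opposite homozygotes cost two.

#' Genotype and allele error
#'
#' `genotype_error` is the proportion of calls that differ from truth.
#' `allele_error` is `sum(|truth - predicted|) / (2 * N)`: the absolute
#' dosage difference is exactly the number of mismatched alleles out of
#' the two carried by a diploid call. Consequently
#' `genotype_error / 2 <= allele_error <= genotype_error` always holds.
#'
#' @param truth,predicted equal-length integer vectors of genotypes in
#'   `{0, 1, 2}`, no missing values.
#' @return fraction in \[0, 1\].
#' @export
genotype_error <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  mean(truth != predicted)
}

#' @rdname genotype_error
#' @export
allele_error <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length")
  sum(abs(truth - predicted)) / (2 * length(truth))
}

#' Masked-imputation evaluation
#'
#' The standard accuracy protocol: draw `n_mask` random known genotypes
#' ([make_mask()]), set them to missing, rebuild the LD index on the
#' masked matrix, impute, and compare with the hidden truth. Reports
#' genotype error, allele error, the 3x3 true-vs-imputed confusion table,
#' and genotype error stratified by MAF in 5% bins (MAF taken from the
#' matrix before masking).
#'
#' @param gm a [geno_matrix].
#' @param method `"mode"`, `"knni"` or `"ldknni"`.
#' @param k,l,c engine parameters (see [impute_genotypes()]).
#' @param n_mask number of genotypes to mask (default 10000).
#' @param seed RNG seed for the mask.
#' @param full if `TRUE`, also impute every originally missing entry and
#'   return the complete matrix in `$imputed` (default `FALSE`: only the
#'   masked coordinates are predicted, which is all the scores need).
#' @return an object of class `imputation_report`: list with `method`,
#'   `params`, `n_mask`, `seed`, `genotype_error`, `allele_error`,
#'   `confusion` (3x3 matrix, rows = truth), `per_maf_bin` (data.frame:
#'   bin, n_masked, genotype_error), `mask`, `predicted`, and `imputed`
#'   (`NULL` unless `full`).
#' @export
masked_evaluation <- function(gm, method = "ldknni", k = NULL, l = NULL,
                              c = 1, n_mask = 10000, seed = 1,
                              full = FALSE) {
  mask <- make_mask(gm, n_mask, seed)
  masked <- apply_mask(gm, mask)
  index <- if (method == "ldknni")
    build_ld_index(masked, if (is.null(l)) 20 else l)
  pred <- .predict_at(masked, mask$coords, method, k = k, l = l, c = c,
                      index = index)
  confusion <- table(factor(mask$truth, levels = 0:2),
                     factor(pred, levels = 0:2))
  confusion <- unclass(confusion)
  dimnames(confusion) <- list(truth = 0:2, imputed = 0:2)
  maf <- snp_maf(gm)
  bin <- cut(maf[mask$coords[, 2L]],
             breaks = seq(0, 0.5, by = 0.05), right = FALSE,
             include.lowest = FALSE)
  # the [0.45, 0.5] top bin is closed so MAF = 0.5 lands in it
  bin[!is.na(maf[mask$coords[, 2L]]) & maf[mask$coords[, 2L]] == 0.5] <-
    "[0.45,0.5)"
  wrong <- mask$truth != pred
  per_bin <- data.frame(
    bin = levels(bin),
    n_masked = as.integer(table(bin)),
    genotype_error = as.numeric(tapply(wrong, bin, mean)),
    row.names = NULL)
  imputed <- NULL
  if (full) {
    filled <- .fill(masked, mask$coords, pred)
    imputed <- impute_genotypes(filled, method, k = k, l = l, c = c)
  }
  structure(list(method = method,
                 params = list(k = k, l = l, c = c),
                 n_mask = n_mask, seed = seed,
                 genotype_error = genotype_error(mask$truth, pred),
                 allele_error = allele_error(mask$truth, pred),
                 confusion = confusion, per_maf_bin = per_bin,
                 mask = mask, predicted = pred, imputed = imputed),
            class = "imputation_report")
}

#' @export
print.imputation_report <- function(x, ...) {
  cat(sprintf("imputation_report: %s on %d masked genotypes (seed %d)\n",
              x$method, x$n_mask, x$seed))
  cat(sprintf("  genotype error: %.4f   allele error: %.4f\n",
              x$genotype_error, x$allele_error))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Allele-frequency bias of imputation
#'
#' Quantifies how imputation distorts minor-allele-frequency estimates.
#' The SNPs with zero missing data are identified; `mask_fraction` of
#' their genotypes are hidden uniformly at random; each method imputes the
#' hidden entries using the FULL masked matrix (incomplete SNPs still
#' inform the LD index and the distances); and per complete SNP the MAF of
#' the original data is compared with the MAF of the data with imputed
#' values at the hidden coordinates. The signed deviation convention is
#' `imputed - true`, so a negative mean means the method pulls MAF
#' downward.
#'
#' @param gm a [geno_matrix] with at least one SNP free of missing data.
#' @param methods character vector of engines to evaluate.
#' @param mask_fraction fraction of the complete SNPs' genotypes to hide
#'   (default 0.20).
#' @param k,l,c engine parameters; `NULL` uses each engine's default.
#' @param seed RNG seed.
#' @return list with `per_snp` (data.frame: method, snp, true_maf,
#'   imputed_maf) and `summary` (data.frame: method, mean_bias,
#'   mean_abs_bias, max_abs_bias).
#' @export
maf_bias_experiment <- function(gm, methods = c("mode", "knni", "ldknni"),
                                mask_fraction = 0.20, k = NULL, l = NULL,
                                c = 1, seed = 1) {
  complete <- which(colSums(is.na(gm$dosage)) == 0L)
  if (length(complete) == 0L)
    stop("no SNP is free of missing data; supply a matrix with complete SNPs ",
         "(e.g. filter samples first)")
  cells <- as.matrix(expand.grid(sample = seq_len(n_samples(gm)),
                                 snp = complete))
  n_hide <- floor(nrow(cells) * mask_fraction)
  sel <- withr::with_seed(seed, sample(nrow(cells), n_hide))
  coords <- cells[sel, , drop = FALSE]
  dimnames(coords) <- NULL
  mask <- structure(list(coords = coords, truth = gm$dosage[coords]),
                    class = "mask_set")
  masked <- apply_mask(gm, mask)
  index <- if ("ldknni" %in% methods)
    build_ld_index(masked, if (is.null(l)) 20 else l)
  true_maf <- snp_maf(gm)[complete]
  per_snp <- list()
  summary_rows <- list()
  for (m in methods) {
    pred <- .predict_at(masked, coords, m, k = k, l = l, c = c,
                        index = if (m == "ldknni") index)
    filled <- .fill(masked, coords, pred)
    imp_maf <- snp_maf(filled[, complete])
    bias <- imp_maf - true_maf
    per_snp[[m]] <- data.frame(method = m, snp = snp_ids(gm)[complete],
                               true_maf = true_maf, imputed_maf = imp_maf,
                               row.names = NULL)
    summary_rows[[m]] <- data.frame(method = m, mean_bias = mean(bias),
                                    mean_abs_bias = mean(abs(bias)),
                                    max_abs_bias = max(abs(bias)))
  }
  list(per_snp = do.call(rbind, per_snp),
       summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)))
}

#' Neighbour overlap between kNNi and LD-kNNi
#'
#' Diagnostic for how different the two engines' neighbourhoods are. For
#' each masked coordinate both neighbour sets are computed with the same
#' `k`; the histogram of intersection sizes (0..k) is returned, along with
#' the mean LD-restricted distance (`d_l`, the LD-kNNi metric) from the
#' target sample to each engine's chosen neighbours -- a large gap means
#' the genome-wide neighbours are far from the target at the SNPs that
#' matter for the imputed locus.
#'
#' @param gm a [geno_matrix] (already containing the missingness of
#'   interest; typically a masked matrix).
#' @param mask a [make_mask()] result: the coordinates to diagnose.
#' @param k neighbour count for both engines (default 5).
#' @param l,c LD-kNNi parameters.
#' @return list with `histogram` (named integer vector over 0..k),
#'   `mean_dl_knni`, `mean_dl_ldknni`.
#' @export
neighbor_overlap <- function(gm, mask, k = 5, l = 20, c = 1) {
  stopifnot(k >= 1)
  masked <- apply_mask(gm, mask)
  G <- masked$dosage
  index <- build_ld_index(masked, l)
  dist <- pairwise_sample_distance(masked)
  D <- dist$d
  D[dist$n == 0L] <- NA_real_
  diag(D) <- NA_real_
  obs <- !is.na(G)
  ind <- .dosage_indicators(G)
  coords <- mask$coords
  overlap <- integer(nrow(coords))
  dl_knni <- dl_ldknni <- rep(NA_real_, nrow(coords))
  for (p in unique(coords[, 2L])) {
    rows <- which(coords[, 2L] == p)
    S <- coords[rows, 1L]
    Lp <- index$neighbors[[p]]
    cand_all <- which(obs[, p])
    if (length(Lp) == 0L) {
      Dl <- matrix(c, length(S), nrow(G))
    } else {
      numer <- tcrossprod(ind$I0[S, Lp, drop = FALSE],
                          ind$I1[, Lp, drop = FALSE] + 2 * ind$I2[, Lp, drop = FALSE]) +
        tcrossprod(ind$I1[S, Lp, drop = FALSE],
                   ind$I0[, Lp, drop = FALSE] + ind$I2[, Lp, drop = FALSE]) +
        tcrossprod(ind$I2[S, Lp, drop = FALSE],
                   2 * ind$I0[, Lp, drop = FALSE] + ind$I1[, Lp, drop = FALSE])
      n_ovl <- tcrossprod(ind$M[S, Lp, drop = FALSE], ind$M[, Lp, drop = FALSE])
      Dl <- c + numer / n_ovl
      Dl[n_ovl == 0] <- c
    }
    for (ii in seq_along(rows)) {
      s <- S[ii]
      cand <- cand_all[cand_all != s]
      if (length(cand) == 0L) next
      dg <- D[s, cand]
      keep <- !is.na(dg)
      nb_knni <- {
        cg <- cand[keep]
        dgk <- dg[keep]
        if (length(cg)) cg[order(dgk, cg)[seq_len(min(k, length(cg)))]] else integer(0)
      }
      dl <- Dl[ii, cand]
      nb_ld <- cand[order(dl, cand)[seq_len(min(k, length(cand)))]]
      overlap[rows[ii]] <- length(intersect(nb_knni, nb_ld))
      if (length(nb_knni)) dl_knni[rows[ii]] <- mean(Dl[ii, nb_knni])
      dl_ldknni[rows[ii]] <- mean(Dl[ii, nb_ld])
    }
  }
  hist <- table(factor(overlap, levels = 0:k))
  list(histogram = stats::setNames(as.integer(hist), names(hist)),
       mean_dl_knni = mean(dl_knni, na.rm = TRUE),
       mean_dl_ldknni = mean(dl_ldknni, na.rm = TRUE))
}

#' Probability that LD partners share the target's chromosome
#'
#' For each rank r = 1..l, the fraction of SNPs whose rank-r LD partner
#' carries the same chromosome label. With real linkage most strong LD is
#' intra-chromosomal at top ranks; the package's block simulator
#' reproduces this when blocks are nested in chromosomes.
#'
#' @param gm a [geno_matrix] with chromosome labels.
#' @param index an `ld_index` built from `gm` (default: built at l = 20).
#' @return data.frame with `rank` and `same_chromosome` fraction.
#' @export
same_chromosome_probability <- function(gm, index = NULL) {
  if (is.null(gm$chrom)) stop("genotype matrix has no chromosome labels")
  if (is.null(index)) index <- build_ld_index(gm, 20)
  l_max <- max(lengths(index$neighbors))
  out <- vapply(seq_len(l_max), function(r) {
    has <- lengths(index$neighbors) >= r
    nbr <- vapply(index$neighbors[has], `[`, integer(1), r)
    mean(gm$chrom[nbr] == gm$chrom[has])
  }, numeric(1))
  data.frame(rank = seq_len(l_max), same_chromosome = out)
}
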