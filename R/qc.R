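# Dataset-preparation filters typical of GBS genotype matrices:
# missingness, MAF, exact Hardy-Weinberg heterozygote-excess test, and
# clone pruning by allele sharing.

#' Filter SNPs and samples by missing-data fraction
#'
#' SNP columns whose missing fraction exceeds `max_missing_snp` are removed
#' first; sample rows whose missing fraction (computed over the surviving
#' SNPs) exceeds `max_missing_sample` are removed second. This fixed order
#' matches the usual GBS pipeline convention of cleaning markers before
#' samples.
#'
#' @param gm a [geno_matrix].
#' @param max_missing_snp maximum tolerated missing fraction per SNP
#'   (default 0.20).
#' @param max_missing_sample maximum tolerated missing fraction per sample
#'   (default 0.20).
#' @return the filtered [geno_matrix].
#' @export
filter_missingness <- function(gm, max_missing_snp = 0.20,
                               max_missing_sample = 0.20) {
  stopifnot(max_missing_snp >= 0, max_missing_snp <= 1,
            max_missing_sample >= 0, max_missing_sample <= 1)
  snp_miss <- colMeans(is.na(gm$dosage))
  keep_snp <- snp_miss <= max_missing_snp
  if (!any(keep_snp))
    stop("all SNPs exceed max_missing_snp = ", max_missing_snp,
         "; raise the threshold")
  gm <- gm[, keep_snp]
  samp_miss <- rowMeans(is.na(gm$dosage))
  keep_samp <- samp_miss <= max_missing_sample
  if (!any(keep_samp))
    stop("all samples exceed max_missing_sample = ", max_missing_sample,
         "; raise the threshold")
  gm[keep_samp, ]
}

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed per SNP over non-missing calls as `min(f, 1 - f)` where
#' `f = sum(dosage) / (2 * n_nonmissing)`. SNPs with MAF below `min_maf`
#' (including monomorphic SNPs) are removed. SNPs with no non-missing calls
#' are removed as well.
#'
#' @param gm a [geno_matrix].
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return the filtered [geno_matrix].
#' @export
filter_maf <- function(gm, min_maf = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 1)
  maf <- snp_maf(gm)
  gm[, !is.na(maf) & maf >= min_maf]
}

#' Exact Hardy-Weinberg test for heterozygote excess
#'
#' One-sided exact test (conditional on observed allele counts, in the
#' style of Wigginton et al.'s exact HWE test) of whether the observed
#' heterozygote count is larger than expected under Hardy-Weinberg
#' equilibrium. Excess heterozygosity is the typical signature of collapsed
#' paralogs in GBS data. The p-value is the probability, under HWE and the
#' observed allele counts, of a heterozygote count greater than or equal to
#' the observed one.
#'
#' @param n0,n1,n2 observed counts of dosage-0 homozygotes, heterozygotes,
#'   and dosage-2 homozygotes.
#' @return p-value; `NA` when the test is undefined (one allele absent).
#' @export
hwe_exact_excess_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na_ <- n1 + 2L * n2           # count of one allele
  nb_ <- n1 + 2L * n0           # and of the other
  if (na_ == 0L || nb_ == 0L) return(NA_real_)
  rare <- min(na_, nb_)
  hets <- seq.int(rare %% 2L, rare, by = 2L)  # feasible het counts, same parity
  # log P(n1 = h | allele counts) up to a constant:
  #   n! / (n0! n1! n2!) * 2^n1, with n0/n2 determined by h
  logp <- vapply(hets, function(h) {
    h0 <- (nb_ - h) / 2
    h2 <- (na_ - h) / 2
    h * log(2) - lgamma(h + 1) - lgamma(h0 + 1) - lgamma(h2 + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  sum(p[hets >= n1])
}

#' Filter SNPs failing an excess-heterozygosity HWE test
#'
#' Removes SNPs whose one-sided exact heterozygote-excess p-value (see
#' [hwe_exact_excess_p()]) is below `alpha`. SNPs for which the test is
#' undefined (an allele absent) are retained.
#'
#' @param gm a [geno_matrix].
#' @param alpha p-value threshold (default 0.001).
#' @return the filtered [geno_matrix].
#' @export
filter_hwe <- function(gm, alpha = 0.001) {
  stopifnot(alpha >= 0, alpha <= 1)
  p <- apply(gm$dosage, 2L, function(col) {
    hwe_exact_excess_p(sum(col == 0L, na.rm = TRUE),
                       sum(col == 1L, na.rm = TRUE),
                       sum(col == 2L, na.rm = TRUE))
  })
  gm[, is.na(p) | p >= alpha]
}

#' Pairwise allele-sharing similarity (IBS) between samples
#'
#' Identity-by-state similarity `1 - sum(|g_i - g_j|) / (2 * n_overlap)`
#' over pairwise-complete SNPs. Pairs with no overlapping non-missing SNPs
#' get similarity 0 (with a message). Used as the clone statistic: for the
#' near-identical pairs that clone pruning targets, IBS and pedigree-style
#' IBD estimates agree, and IBS needs no reference allele frequencies.
#'
#' @param gm a [geno_matrix].
#' @return symmetric samples-by-samples matrix of similarities in \[0, 1\]
#'   with 1 on the diagonal.
#' @export
ibs_matrix <- function(gm) {
  dn <- pairwise_sample_distance(gm)
  sim <- 1 - dn$d / 2
  if (any(dn$n == 0L & upper.tri(dn$n))) {
    message("ibs_matrix: ", sum(dn$n == 0L & upper.tri(dn$n)),
            " sample pair(s) share no observed SNPs; similarity set to 0")
  }
  sim[dn$n == 0L] <- 0
  diag(sim) <- 1
  dimnames(sim) <- list(sample_ids(gm), sample_ids(gm))
  sim
}

#' Remove clonal duplicates, keeping the most complete sample
#'
#' Samples are grouped by single linkage over pairs whose allele-sharing
#' similarity ([ibs_matrix()]) exceeds `threshold`; within each group only
#' the sample with the fewest missing genotypes is retained (ties broken by
#' sample order). Single linkage makes clone groups transitive: if A~B and
#' B~C, all three form one group.
#'
#' @param gm a [geno_matrix].
#' @param threshold similarity above which a pair is considered clonal
#'   (default 0.9).
#' @return the pruned [geno_matrix].
#' @export
prune_clones <- function(gm, threshold = 0.9) {
  stopifnot(threshold >= 0, threshold <= 1)
  sim <- ibs_matrix(gm)
  adj <- sim > threshold
  diag(adj) <- FALSE
  if (!any(adj)) return(gm)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  n_miss <- rowSums(is.na(gm$dosage))
  keep <- rep(TRUE, n_samples(gm))
  for (grp in split(seq_along(comp), comp)) {
    if (length(grp) < 2L) next
    best <- grp[which.min(n_miss[grp])]
    keep[setdiff(grp, best)] <- FALSE
  }
  gm[keep, ]
}

#' Run the full QC pipeline
#'
#' Applies, in order: missingness filter, MAF filter, HWE
#' heterozygote-excess filter, clone pruning. Any step can be disabled by
#' passing `NULL` for its threshold. The order is configurable via `steps`.
#'
#' @param gm a [geno_matrix].
#' @param max_missing_snp,max_missing_sample see [filter_missingness()];
#'   `NULL` skips the step.
#' @param min_maf see [filter_maf()]; `NULL` skips.
#' @param hwe_alpha see [filter_hwe()]; `NULL` skips.
#' @param clone_threshold see [prune_clones()]; `NULL` skips.
#' @param steps character vector giving the step order; a subset of
#'   `c("missingness", "maf", "hwe", "clones")`.
#' @return the filtered [geno_matrix].
#' @export
qc_pipeline <- function(gm, max_missing_snp = 0.20, max_missing_sample = 0.20,
                        min_maf = 0.01, hwe_alpha = 0.001,
                        clone_threshold = 0.9,
                        steps = c("missingness", "maf", "hwe", "clones")) {
  steps <- match.arg(steps, c("missingness", "maf", "hwe", "clones"),
                     several.ok = TRUE)
  for (s in steps) {
    gm <- switch(s,
      missingness = if (is.null(max_missing_snp)) gm else
        filter_missingness(gm, max_missing_snp, max_missing_sample),
      maf = if (is.null(min_maf)) gm else filter_maf(gm, min_maf),
      hwe = if (is.null(hwe_alpha)) gm else filter_hwe(gm, hwe_alpha),
      clones = if (is.null(clone_threshold)) gm else
        prune_clones(gm, clone_threshold))
  }
  gm
}
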