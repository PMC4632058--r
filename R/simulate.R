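# Block-LD genotype simulator. Each LD block has a small pool of founder
# haplotypes; every sample draws two founder haplotypes per block. A small
# pool means few distinct haplotypes segregate, i.e. strong within-block
# LD; blocks are independent (unless recomb_rate < 1 chains founder choices
# along a chromosome), giving zero between-block LD in expectation. This
# is deliberately a caricature of a diverse, heterozygous GBS panel: it
# has the features the imputation engines exploit (local LD, sharing of
# haplotypes between samples, MCAR missingness) with a closed-form LD
# oracle, but none of the demographic realism of a coalescent simulation.

#' Simulation settings for the block-LD genotype generator
#'
#' @param n_samples,n_snps matrix dimensions (default 1000 x 1000, the
#'   package's standard evaluation scenario).
#' @param n_chromosomes chromosome labels are assigned to contiguous runs
#'   of blocks (default 5).
#' @param block_size SNPs per LD block (default 20).
#' @param founder_pool number of founder haplotypes per block (default 8;
#'   smaller means stronger LD).
#' @param maf_low,maf_high founder site allele frequencies are drawn
#'   uniformly from this range (default 0.05-0.5).
#' @param recomb_rate probability that a haplotype re-draws its founder at
#'   each block boundary within a chromosome (default 1: blocks
#'   independent).
#' @param missing_rate i.i.d. (MCAR) missingness applied to the observed
#'   matrix (default 0.10).
#' @param n_clones number of samples to duplicate (default 0). Clones are
#'   copies of the first `n_clones` samples appended as new rows before
#'   missingness is applied.
#' @param n_complete_snps number of SNPs exempted from missingness
#'   (default 0). Useful for allele-frequency-bias experiments, which need
#'   a core of fully observed SNPs alongside ordinary incomplete ones.
#' @param seed RNG seed; the whole simulation is deterministic given the
#'   config.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 1000, n_snps = 1000, n_chromosomes = 5,
                       block_size = 20, founder_pool = 8,
                       maf_low = 0.05, maf_high = 0.5, recomb_rate = 1,
                       missing_rate = 0.10, n_clones = 0,
                       n_complete_snps = 0, seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              block_size = as.integer(block_size),
              founder_pool = as.integer(founder_pool),
              maf_low = maf_low, maf_high = maf_high,
              recomb_rate = recomb_rate, missing_rate = missing_rate,
              n_clones = as.integer(n_clones),
              n_complete_snps = as.integer(n_complete_snps),
              seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 1, cfg$n_snps >= 1, cfg$block_size >= 1,
            cfg$founder_pool >= 2,
            cfg$maf_low >= 0, cfg$maf_high <= 1, cfg$maf_low <= cfg$maf_high,
            cfg$recomb_rate >= 0, cfg$recomb_rate <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$n_clones >= 0, cfg$n_complete_snps >= 0,
            cfg$n_complete_snps <= cfg$n_snps)
  class(cfg) <- "sim_config"
  cfg
}

# Founder haplotype pools, one h x block_size 0/1 matrix per block.
# Drawn under the config seed BEFORE anything else, so that
# expected_block_r2() can reproduce them independently of simulate().
.draw_founders <- function(cfg) {
  n_blocks <- ceiling(cfg$n_snps / cfg$block_size)
  withr::with_seed(cfg$seed, {
    lapply(seq_len(n_blocks), function(b) {
      bs <- min(cfg$block_size, cfg$n_snps - (b - 1L) * cfg$block_size)
      q <- stats::runif(bs, cfg$maf_low, cfg$maf_high)
      matrix(stats::rbinom(cfg$founder_pool * bs, 1L, rep(q, each = cfg$founder_pool)),
             nrow = cfg$founder_pool, ncol = bs)
    })
  })
}

#' Simulate a genotype matrix with block-LD structure
#'
#' See [sim_config()] for the generative model. Returns both the complete
#' truth and the observed matrix with MCAR missingness, plus the founder
#' pools (the inputs to the analytic LD oracle
#' [expected_block_r2()]).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `truth` (complete [geno_matrix]), `observed`
#'   ([geno_matrix] with missing entries), `founders` (list of per-block
#'   founder haplotype matrices), and `config`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  founders <- .draw_founders(cfg)
  n_blocks <- length(founders)
  # founders use cfg$seed (shared with expected_block_r2); sample assembly
  # and missingness use a derived stream
  withr::with_seed(cfg$seed + 1L, {
    chrom_of_block <- rep(seq_len(cfg$n_chromosomes),
                          each = ceiling(n_blocks / cfg$n_chromosomes),
                          length.out = n_blocks)
    n <- cfg$n_samples
    h <- cfg$founder_pool
    # founder indices per haplotype copy, chained along chromosomes
    draw_chain <- function() {
      idx <- matrix(0L, n, n_blocks)
      for (b in seq_len(n_blocks)) {
        fresh <- sample.int(h, n, replace = TRUE)
        if (b > 1L && chrom_of_block[b] == chrom_of_block[b - 1L] &&
            cfg$recomb_rate < 1) {
          carry <- stats::runif(n) >= cfg$recomb_rate
          idx[, b] <- ifelse(carry, idx[, b - 1L], fresh)
        } else {
          idx[, b] <- fresh
        }
      }
      idx
    }
    idx1 <- draw_chain()
    idx2 <- draw_chain()
    blocks <- lapply(seq_len(n_blocks), function(b) {
      founders[[b]][idx1[, b], , drop = FALSE] +
        founders[[b]][idx2[, b], , drop = FALSE]
    })
    G <- do.call(cbind, blocks)
    chrom <- rep(chrom_of_block, vapply(founders, ncol, integer(1)))
    if (cfg$n_clones > 0) {
      nc <- min(cfg$n_clones, n)
      G <- rbind(G, G[seq_len(nc), , drop = FALSE])
    }
    samples <- c(paste0("S", seq_len(n)),
                 if (cfg$n_clones > 0) paste0("S", seq_len(min(cfg$n_clones, n)), "_clone"))
    snps <- paste0("snp", seq_len(cfg$n_snps))
    truth <- geno_matrix(G, samples = samples, snps = snps,
                         chrom = paste0("chr", chrom),
                         pos = stats::ave(seq_len(cfg$n_snps), chrom,
                                          FUN = seq_along))
    obs <- G
    if (cfg$missing_rate > 0) {
      maskable <- seq_len(cfg$n_snps)
      if (cfg$n_complete_snps > 0)
        maskable <- setdiff(maskable,
                            sample.int(cfg$n_snps, cfg$n_complete_snps))
      miss <- matrix(stats::runif(nrow(G) * length(maskable)) < cfg$missing_rate,
                     nrow = nrow(G))
      obs[, maskable][miss] <- NA_integer_
    }
    observed <- geno_matrix(obs, samples = samples, snps = snps,
                            chrom = truth$chrom, pos = truth$pos)
    list(truth = truth, observed = observed, founders = founders,
         config = cfg)
  })
}

#' Analytic within-block LD under the founder-pool model
#'
#' Population (not sample) composite r^2 between the sites of one block,
#' computed in closed form from the founder haplotype pool. A sample's two
#' haplotypes are i.i.d. uniform draws from the pool, so the dosage
#' covariance between two sites is twice the haplotype covariance and the
#' dosage correlation equals the haplotype correlation over the uniform
#' founder distribution. Sites with zero variance in the pool get r^2 = 0
#' against everything (diagonal 1 where defined).
#'
#' @param x a [sim_config()] (pools are re-derived from its seed) or a
#'   single founder haplotype matrix as returned in
#'   `simulate_genotypes()$founders`.
#' @param block which block to compute when `x` is a config (default 1).
#' @return sites-by-sites matrix of population r^2 values.
#' @export
expected_block_r2 <- function(x, block = 1L) {
  H <- if (inherits(x, "sim_config")) .draw_founders(x)[[block]] else x
  h <- nrow(H)
  p <- colMeans(H)
  cov <- crossprod(H) / h - outer(p, p)
  v <- p * (1 - p)
  r2 <- cov^2 / outer(v, v)
  r2[outer(v, v) == 0] <- 0
  diag(r2)[v > 0] <- 1
  r2
}
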