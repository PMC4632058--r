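test_that("genotype and allele error implement the stated definitions", {
  expect_equal(genotype_error(c(0, 1, 2, 1), c(0, 1, 2, 1)), 0)
  expect_equal(genotype_error(c(0, 2), c(2, 0)), 1)
  expect_equal(genotype_error(c(0, 1, 2, 2), c(0, 0, 2, 1)), 0.5)
  expect_equal(allele_error(c(0, 1, 2, 2), c(0, 0, 2, 1)), 0.25)
  expect_equal(allele_error(0, 2), 1)
  expect_error(genotype_error(c(0, 1), 0), "length")
  expect_error(allele_error(c(0, 1), 0), "length")
})

test_that("allele error is between half of and all of genotype error", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      truth <- sample(0:2, 200, replace = TRUE)
      pred <- sample(0:2, 200, replace = TRUE)
    })
    ge <- genotype_error(truth, pred)
    ae <- allele_error(truth, pred)
    expect_gte(ae, ge / 2)
    expect_lte(ae, ge)
  }
})

test_that("masked evaluation scores, stratifies and conserves the mask", {
  cfg <- sim_config(n_samples = 80, n_snps = 100, block_size = 10,
                    founder_pool = 4, missing_rate = 0.1, seed = 30)
  gm <- simulate_genotypes(cfg)$observed
  rep <- masked_evaluation(gm, "ldknni", n_mask = 300, seed = 31)
  expect_equal(sum(rep$confusion), 300)
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(rep$mask$truth, levels = 0:2)))))
  expect_equal(sum(rep$per_maf_bin$n_masked), 300)
  expect_gte(rep$allele_error, rep$genotype_error / 2)
  expect_lte(rep$allele_error, rep$genotype_error)
  # errors recomputable from the stored predictions
  expect_equal(rep$genotype_error,
               mean(rep$predicted != rep$mask$truth))

  # full = TRUE returns a complete matrix agreeing on unmasked known calls
  rep_f <- masked_evaluation(gm, "mode", n_mask = 100, seed = 32, full = TRUE)
  expect_false(anyNA(rep_f$imputed$dosage))
  known <- !is.na(gm$dosage)
  known[rep_f$mask$coords] <- FALSE
  expect_identical(rep_f$imputed$dosage[known], gm$dosage[known])
})

test_that("clone-rich data is imputed without error by LD-kNNi", {
  # a matrix whose SNPs are all copies of one balanced column: the LD
  # partners determine every genotype exactly, so imputation is lossless
  col <- rep(0:2, each = 10L)
  d <- matrix(rep(col, 40), ncol = 40)
  gm <- geno_matrix(d)
  rep <- masked_evaluation(gm, "ldknni", k = 1, l = 10, n_mask = 200, seed = 34)
  expect_equal(rep$genotype_error, 0)
  expect_equal(rep$allele_error, 0)
})

test_that("mode-imputation error matches its analytic expectation", {
  # masked entries drawn uniformly from a column are wrong with
  # probability 1 - modal-class frequency
  cfg <- sim_config(n_samples = 200, n_snps = 50, block_size = 5,
                    founder_pool = 6, missing_rate = 0, seed = 35)
  gm <- simulate_genotypes(cfg)$truth
  rep <- masked_evaluation(gm, "mode", n_mask = 2000, seed = 36)
  expected <- mean(sapply(seq_len(50), function(j) {
    col <- gm$dosage[, j]
    1 - max(tabulate(col + 1L, 3L)) / length(col)
  }))
  # binomial noise on 2000 draws plus the slight mode shift from masking
  expect_lt(abs(rep$genotype_error - expected), 4 * sqrt(0.25 / 2000) + 0.01)
})

test_that("evaluation reports are reproducible bit-for-bit per seed", {
  gm <- random_gm(50, 60, miss = 0.1, seed = 37)
  r1 <- masked_evaluation(gm, "ldknni", n_mask = 200, seed = 38)
  r2 <- masked_evaluation(gm, "ldknni", n_mask = 200, seed = 38)
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
})

test_that("the MAF-bias experiment masks only complete SNPs and signs bias as imputed - true", {
  cfg <- sim_config(n_samples = 150, n_snps = 120, block_size = 10,
                    founder_pool = 4, missing_rate = 0.1,
                    n_complete_snps = 30, seed = 40)
  gm <- simulate_genotypes(cfg)$observed
  res <- maf_bias_experiment(gm, methods = c("mode", "ldknni"), seed = 41)
  expect_setequal(unique(res$per_snp$method), c("mode", "ldknni"))
  expect_equal(sum(res$per_snp$method == "mode"), 30)
  with(subset(res$summary, method == "mode"),
       expect_equal(mean_bias,
                    mean(subset(res$per_snp, method == "mode")$imputed_maf -
                           subset(res$per_snp, method == "mode")$true_maf)))
  expect_error(maf_bias_experiment(random_gm(30, 10, miss = 0.9, seed = 1)),
               "complete")
})

test_that("a perfectly recoverable matrix leaves MAF estimates untouched", {
  # all SNPs are copies of one balanced column: imputation is lossless,
  # so imputed and true MAF must coincide exactly
  col <- rep(0:2, each = 12L)
  gm <- geno_matrix(matrix(rep(col, 30), ncol = 30))
  res <- maf_bias_experiment(gm, methods = "ldknni", mask_fraction = 0.2,
                             k = 1, seed = 43)
  expect_equal(res$per_snp$imputed_maf, res$per_snp$true_maf, tolerance = 1e-12)
  expect_equal(res$summary$mean_bias, 0, tolerance = 1e-12)
})

test_that("neighbour overlap counts agree with a brute-force recomputation", {
  gm <- random_gm(25, 40, miss = 0.15, seed = 44)
  mask <- make_mask(gm, 40, seed = 45)
  ov <- neighbor_overlap(gm, mask, k = 3, l = 5)
  expect_equal(sum(ov$histogram), 40)
  expect_named(ov$histogram, as.character(0:3))

  masked <- apply_mask(gm, mask)
  G <- masked$dosage
  idx <- oracle_ld_index(G, 5)
  brute <- sapply(seq_len(40), function(r) {
    s <- mask$coords[r, 1]; p <- mask$coords[r, 2]
    cand <- c(); dg <- c(); dl <- c()
    for (t in seq_len(25)) {
      if (t == s || is.na(G[t, p])) next
      g <- oracle_taxicab(G, s, t)
      if (g$n == 0L) next
      l_ <- oracle_taxicab(G, s, t, snps = idx[[p]])
      cand <- c(cand, t); dg <- c(dg, g$d)
      dl <- c(dl, if (l_$n == 0L) 1 else 1 + l_$d)
    }
    a <- cand[order(dg, cand)[seq_len(min(3, length(cand)))]]
    b <- cand[order(dl, cand)[seq_len(min(3, length(cand)))]]
    length(intersect(a, b))
  })
  expect_equal(unname(ov$histogram),
               unname(as.integer(table(factor(brute, levels = 0:3)))))
})

test_that("same-chromosome probability is 1 on one chromosome and enriched with real linkage", {
  cfg <- sim_config(n_samples = 100, n_snps = 60, n_chromosomes = 1,
                    block_size = 10, founder_pool = 4, missing_rate = 0.05,
                    seed = 46)
  gm <- simulate_genotypes(cfg)$observed
  pr <- same_chromosome_probability(gm, build_ld_index(gm, 5))
  expect_true(all(pr$same_chromosome == 1))

  cfg2 <- sim_config(n_samples = 300, n_snps = 80, n_chromosomes = 2,
                     block_size = 40, founder_pool = 3, missing_rate = 0.05,
                     seed = 47)
  gm2 <- simulate_genotypes(cfg2)$observed
  pr2 <- same_chromosome_probability(gm2, build_ld_index(gm2, 5))
  # strong within-block LD: the rank-1 partner is nearly always cis
  expect_gt(pr2$same_chromosome[1], 0.5)
  expect_true(all(pr2$same_chromosome >= 0 & pr2$same_chromosome <= 1))

  expect_error(same_chromosome_probability(random_gm(5, 5, 0, 1)),
               "chromosome")
})
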