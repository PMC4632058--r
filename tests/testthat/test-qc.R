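test_that("missingness filter drops SNPs first, then samples", {
  # one SNP 40% missing at threshold 0.20 -> dropped
  d <- matrix(0L, 5, 4)
  d[1:2, 2] <- NA_integer_
  gm <- geno_matrix(d)
  out <- filter_missingness(gm, 0.20, 0.20)
  expect_equal(snp_ids(out), c("snp1", "snp3", "snp4"))
  expect_equal(n_samples(out), 5L)

  # fully observed matrix unchanged
  gm2 <- random_gm(6, 5, miss = 0, seed = 1)
  expect_identical(filter_missingness(gm2)$dosage, gm2$dosage)

  # a sample that only fails before SNP removal is kept: its missingness
  # is concentrated in a column that is dropped first
  d <- matrix(0L, 10, 10)
  d[1, 1:3] <- NA_integer_      # sample 1: 30% missing overall
  d[2:10, 1] <- NA_integer_     # snp 1: 100% missing -> dropped first
  out <- filter_missingness(geno_matrix(d), 0.20, 0.25)
  expect_equal(n_samples(out), 10L)   # sample 1 is 2/9 = 22% after the drop
  expect_equal(n_snps(out), 9L)
})

test_that("missingness filter agrees with a brute-force recount", {
  gm <- random_gm(50, 100, miss = 0.18, seed = 7)
  out <- filter_missingness(gm, 0.20, 0.20)
  keep_snp <- sapply(seq_len(100), function(j) mean(is.na(gm$dosage[, j])) <= 0.20)
  sub <- gm$dosage[, keep_snp, drop = FALSE]
  keep_samp <- sapply(seq_len(50), function(i) mean(is.na(sub[i, ])) <= 0.20)
  expect_identical(out$dosage, sub[keep_samp, , drop = FALSE])
})

test_that("MAF filter removes rare and monomorphic SNPs", {
  gm <- geno_matrix(cbind(c(0, 0, 0, 0, 0, 1),   # f = 1/12, kept at 0.01
                          rep(0L, 6),            # monomorphic -> dropped
                          c(0, 1, 1, 2, 2, 2)))  # common, kept
  out <- filter_maf(gm, 0.01)
  expect_equal(snp_ids(out), c("snp1", "snp3"))

  gm2 <- random_gm(40, 60, miss = 0.1, seed = 9)
  out2 <- filter_maf(gm2, 0.1)
  brute <- sapply(seq_len(60), function(j) {
    x <- gm2$dosage[, j]
    x <- x[!is.na(x)]
    f <- sum(x) / (2 * length(x))
    min(f, 1 - f) >= 0.1
  })
  expect_equal(snp_ids(out2), snp_ids(gm2)[brute])
})

test_that("exact heterozygote-excess test matches full enumeration", {
  cases <- rbind(c(25, 50, 25), c(0, 100, 0), c(40, 20, 40), c(5, 10, 5),
                 c(1, 1, 1), c(0, 3, 7), c(12, 0, 3))
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_excess_p(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle_hwe_excess(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-12, info = paste(cases[i, ], collapse = ","))
  }
  # HW-proportioned data is retained, all-het data removed at alpha 0.001
  expect_gt(hwe_exact_excess_p(25, 50, 25), 0.001)
  expect_lt(hwe_exact_excess_p(0, 100, 0), 0.001)
  # monomorphic: test undefined -> NA -> retained
  expect_true(is.na(hwe_exact_excess_p(10, 0, 0)))
})

test_that("HWE filter removes excess-het SNPs and keeps degenerate ones", {
  d <- cbind(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)),  # in HWE
             rep(1L, 100),                              # all het
             rep(0L, 100))                              # monomorphic
  out <- filter_hwe(geno_matrix(d), 0.001)
  expect_equal(snp_ids(out), c("snp1", "snp3"))
})

test_that("clone pruning keeps the most complete sample of each group", {
  base <- random_gm(1, 40, miss = 0, seed = 4)$dosage[1, ]
  other <- random_gm(1, 40, miss = 0, seed = 5)$dosage[1, ]
  d <- rbind(a = base, b = base, c = other)
  d["b", 1:5] <- NA_integer_
  out <- prune_clones(geno_matrix(d), 0.9)
  expect_equal(sample_ids(out), c("a", "c"))

  # ties in completeness go to the first sample
  d2 <- rbind(x = base, y = base)
  expect_equal(sample_ids(prune_clones(geno_matrix(d2), 0.9)), "x")
})

test_that("clone grouping is single-linkage and matches brute force", {
  gm <- random_gm(14, 60, miss = 0.1, seed = 21)
  d <- gm$dosage
  # plant 3 clone pairs (with small missingness differences)
  d <- rbind(d, d[1, ], d[2, ], d[3, ])
  d[15, 1:3] <- NA_integer_
  d[16, 10] <- NA_integer_
  rownames(d) <- paste0("S", seq_len(nrow(d)))
  gm2 <- geno_matrix(d)
  out <- prune_clones(gm2, 0.9)

  sim <- ibs_matrix(gm2)
  expect_true(isSymmetric(sim))
  expect_true(all(sim >= 0 & sim <= 1))
  # brute-force grouping: BFS over the >0.9 graph
  n <- nrow(d)
  grp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sim[i, j] > 0.9) grp[grp == grp[j]] <- grp[i]
  }
  keep <- sapply(unique(grp), function(g) {
    members <- which(grp == g)
    members[which.min(rowSums(is.na(d[members, , drop = FALSE])))]
  })
  expect_equal(sample_ids(out), paste0("S", sort(keep)))
})

test_that("QC filters are idempotent", {
  # MAF, HWE and clone filters are idempotent unconditionally; the
  # missingness filter is a single pass (SNPs then samples), so its
  # idempotence holds when thresholds are not razor-close to the ambient
  # missingness (removing samples re-weights per-SNP fractions), which is
  # the regime tested here
  gm <- random_gm(30, 50, miss = 0.10, seed = 13)
  for (f in list(function(g) filter_missingness(g, 0.20, 0.20),
                 function(g) filter_maf(g, 0.1),
                 function(g) filter_hwe(g, 0.05),
                 function(g) prune_clones(g, 0.9))) {
    once <- f(gm)
    expect_identical(f(once)$dosage, once$dosage)
  }
})

test_that("the pipeline applies steps in the documented order", {
  gm <- random_gm(25, 40, miss = 0.15, seed = 17)
  manual <- prune_clones(filter_hwe(filter_maf(filter_missingness(gm))))
  expect_identical(qc_pipeline(gm)$dosage, manual$dosage)
})
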