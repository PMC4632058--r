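---
title: "LD-informed k-nearest-neighbour genotype imputation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LD-informed k-nearest-neighbour genotype imputation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldknni)
```

## The problem

Reduced-representation sequencing protocols such as genotyping-by-sequencing
(GBS) deliver cheap genome-wide SNP genotypes at the price of a lot of missing
data: read depth varies wildly across sites and samples, so matrices with
10–50% missing calls are normal. Most imputation methods assume ordered
markers, phased reference haplotypes, or inbred material. Diverse,
heterozygous germplasm collections (fruit-tree repositories, outbred crop
panels) violate all three. This package implements imputation that needs only
the genotype matrix itself: no map, no reference panel, no phasing, no marker
order.

Genotypes are coded as minor-allele dosages: 0 (homozygous major), 1
(heterozygous), 2 (homozygous minor), with `NA` for missing. All methods are
invariant to a global 0↔2 recoding of any SNP, because every distance uses
absolute dosage differences; `recode_to_minor()` exists for reporting
purposes (MAF spectra), not for correctness.

## The three engines

**Mode.** Each missing call gets the most frequent observed genotype of its
SNP. No between-sample information; the floor any method must beat.

**kNNi.** For a missing entry (sample *s*, SNP *p*), the distance from *s* to
every other sample is the missing-aware, normalised taxicab distance

$$d_n(s_1, s_2) = \frac{1}{n} \sum_{p \in P} |g(s_1,p) - g(s_2,p)|,$$

summed over the SNPs where both samples are observed (*n* of them; the
normaliser keeps distances comparable between pairs with different overlap).
The *k* nearest samples with an observed genotype at *p* then vote with
weight 1/d:

$$\hat g(s, p) = \arg\max_{a \in \{0,1,2\}} \sum_{t \in N} \frac{1}{d_n(s,t)}\, I(g(t,p) = a).$$

**LD-kNNi.** Genome-wide distance is dominated by SNPs irrelevant to the
target locus. LD-kNNi computes, once per matrix, the *l* SNPs in strongest
LD with each SNP (squared Pearson correlation of dosages, *r²*, over
pairwise-complete samples) and replaces the distance for target SNP *p* by

$$d_l(s_1, s_2) = c + \frac{1}{n} \sum_{q \in L(p)} |g(s_1,q) - g(s_2,q)|,$$

the same taxicab form restricted to the LD set *L(p)*, plus a constant *c*.
With few SNPs in the sum, two samples can be genetically identical on
*L(p)*; the constant keeps every distance positive so the inverse-distance
vote is always defined. Neighbours are therefore chosen per target SNP: two
missing entries of the same sample generally use different neighbours.

### Parameters

* `k` — neighbour count. Defaults: 5 for LD-kNNi, 8 for kNNi. Small *k*
  exploits near-clonal relationships; large *k* averages towards the mode.
* `l` — LD partners per SNP (LD-kNNi only), default 20. Below the typical
  number of informative linked markers the distance gets noisy; far above it
  the metric degrades towards the genome-wide one.
* `c` — additive distance constant, default 1. Any positive value works; the
  vote depends on *c* only through relative weights, and performance is flat
  in a wide range around 1.

All defaults can be replaced by `tune_params()`, which masks known genotypes
and maximises exact-recovery accuracy (below).

## Measuring LD without phase or order

The package's LD statistic is the squared Pearson correlation of 0/1/2
dosage vectors over pairwise-complete samples — the standard composite-LD
surrogate when phase is unknown. Pairs with fewer than `min_overlap = 2`
shared observed samples, or zero variance on the overlap, get *r²* = 0:
correlation is undefined there, and 0 ("useless for prediction") is the
conservative value for a ranking statistic. The matrix is computed from
dense indicator cross-products, so a few thousand SNPs cost seconds.

Within `masked_evaluation()`, `tune_params()` and `maf_bias_experiment()`,
the LD index is always rebuilt **after** masking: hidden truth must not leak
into the feature selection that will be used to recover it.

## Determinism

Every stochastic step takes a seed, and every tie has a documented,
order-independent rule:

* neighbour ties at equal distance → ascending sample index;
* vote ties at equal score → smallest genotype code;
* top-*l* LD ties at equal *r²* → ascending SNP index. *r²* values are
  rounded to 12 decimals before ranking, so values that are equal in exact
  arithmetic but differ in the last bits between summation orders still tie
  (and then break by index) identically on every code path;
* zero-distance neighbours (possible for the genome-wide metric only, since
  d_l ≥ c > 0) → the vote restricts to the zero-distance members,
  unweighted;
* a candidate pair with no shared observed SNP in *L(p)* keeps distance
  exactly *c* and stays eligible;
* a missing entry with no eligible neighbour at all falls back to the column
  mode; a fully missing column is an error.

No chaining: every prediction uses only originally observed data, so
imputation order cannot matter and results are reproducible bit-for-bit.

## Parameter tuning

`tune_params()` draws one mask of known genotypes (default 10,000, capped at
10% of the known entries so tuning does not drown the matrix in extra
missingness), and treats exact-recovery accuracy on that fixed mask as the
objective. One fixed mask — rather than one per candidate — makes parameter
values directly comparable; the cost is a shared sampling error that affects
all candidates equally. Assuming the accuracy surface is unimodal in each
coordinate, each 1-D search brackets geometrically (doubling from the lower
bound until accuracy drops) and finishes with integer ternary search; for
LD-kNNi the k- and l-searches alternate until fixed point (at most 10
sweeps). The defaults (k = 5, l = 20) are evaluated first and the best
*visited* point is returned, so tuning can never return parameters that
score below the defaults on its own mask. On block-LD test matrices the
search recovers the exhaustive-grid optimum (see
`tests/testthat/test-acceptance.R`) while evaluating ~30 of 600 grid points.

## Evaluation framework

`masked_evaluation()` hides `n_mask` random known genotypes, re-imputes
them, and reports genotype error (fraction of wrong calls), allele error
(`sum(|truth − predicted|) / 2N`, the fraction of wrong alleles), the 3×3
confusion table, and genotype error stratified by MAF in 5% bins (MAF taken
before masking). Because a wrong diploid call mismatches one or two alleles,
allele error is always between half of and all of the genotype error.

`maf_bias_experiment()` measures the systematic MAF shift caused by
imputation: it hides 20% of the genotypes of the fully observed SNPs,
imputes using the whole matrix (incomplete SNPs still inform the LD index),
and compares per-SNP MAF before and after, signed as imputed − true.
Mode-like behaviour pulls MAF down (the mode is usually a major-allele-rich
class); the interesting question is how much of that survives in the
LD-aware engine.

`neighbor_overlap()` quantifies how differently the two kNN engines choose
neighbours (intersection histogram at equal *k*, and each engine's mean
LD-restricted distance to its neighbours); `same_chromosome_probability()`
checks, when chromosome labels exist, how often top LD partners are cis —
a sanity check that the LD ranking reflects linkage rather than noise.

## The QC filters

The usual GBS preparation steps, each a single deterministic pass:
missingness (SNPs above the per-SNP threshold first, then samples above the
per-sample threshold on the surviving SNPs), MAF < 0.01 removal, a one-sided
exact Hardy–Weinberg test against heterozygote *excess* (the GBS signature
of collapsed paralogs; exact conditional distribution of the heterozygote
count given allele counts, SNPs with p < 0.001 removed, monomorphic SNPs
retained as the test is undefined), and clone pruning. The clone statistic
is allele-sharing IBS = 1 − Σ|gᵢ−gⱼ|/(2·overlap) — a deliberate, documented
substitute for pedigree-style IBD: at the 0.9 threshold used for clone
detection the two agree, and IBS needs no reference allele frequencies.
Clone groups are single-linkage components of the >threshold graph ("two
or more samples" is transitive), keeping each group's most complete sample.
Note the missingness filter, being one fixed-order pass, is not exactly
idempotent when thresholds sit at the ambient missingness level — removing
samples re-weights per-SNP fractions; the other filters are idempotent
unconditionally.

## The synthetic-data generator

`simulate_genotypes()` produces matrices with the features these methods
exploit, and a closed-form LD oracle. Each LD block of `block_size` SNPs
(default 20) has a pool of `founder_pool` haplotypes (default 8) whose site
frequencies are drawn from U(0.05, 0.5); every sample draws two founder
haplotypes per block, independently across blocks (or chained along
chromosomes when `recomb_rate < 1`). Small pools mean few segregating
haplotypes, i.e. strong within-block LD; between blocks LD is zero in
expectation. Missingness is i.i.d. (MCAR, default 10%), matching the
masking protocol used for evaluation. `expected_block_r2()` returns the
population *r²* of a block directly from its pool, because a sample's two
haplotypes are i.i.d. pool draws, making the dosage correlation equal the
haplotype correlation under the uniform founder distribution.

The standard evaluation scenario used in the acceptance tests and
`scripts/acceptance.R` is 1000 samples × 1000 SNPs (50 blocks over 5
chromosomes), pool 8, 10% missing, with 10,000 masked genotypes — large
enough that error differences of a percentage point are far outside mask
noise, small enough to run in seconds per engine. The MAF-bias scenario
additionally exempts 200 of the 1000 SNPs from missingness
(`n_complete_snps`): with i.i.d. missingness at 10% essentially no SNP of a
1000-sample matrix is complete by chance, whereas real complete-SNP subsets
arise by subsetting samples; exempting a fixed number of SNPs reproduces
the needed mixture of complete and incomplete SNPs without changing the
rest of the regime. The tuning scenario is 100 × 300 so that an exhaustive
k × l grid remains cheap to compare against.

**What the generator does not emulate.** Three things, all consequential
for interpreting results on real data:

1. *No between-sample relatedness.* Founder draws are independent across
   samples, so no pair of samples shares ancestry beyond chance. Real
   germplasm panels are full of relatives and population structure, which is
   precisely the signal genome-wide kNNi feeds on. On this generator kNNi
   therefore barely beats Mode (the genome-wide distance averages 50
   independent blocks and carries almost no information about any one of
   them), whereas on real panels it beats Mode by a few points. LD-kNNi's
   large advantage is unaffected — it relies on local LD, which the
   generator does produce.
2. *MCAR missingness.* Real GBS missingness is depth-dependent and
   correlated along the genome and between technical batches; here it is
   i.i.d., which matches the masking protocol but understates hard cases.
3. *No mutation/genotyping error,* so "clones" are exact duplicates.

Passing tests on this generator therefore demonstrate correctness of the
algorithms and the expected qualitative behaviour of LD-restricted
distances; they are not accuracy forecasts for any particular crop dataset.

## Known limitations

* All-pairs LD is O(m²) in SNPs and is materialised densely: fine to ~20k
  SNPs on a laptop, wasteful beyond; a blocked/threshold variant would be
  the next step for 100k+ marker panels.
* Read-depth information is ignored (dosage calls are taken at face value);
  genotype-likelihood-aware voting would use low-coverage data better.
* The exact-recovery objective used in tuning treats het/hom errors as
  equal; applications that care about allele error specifically may prefer
  re-tuning under that loss.
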