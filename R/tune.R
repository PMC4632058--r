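# Parameter optimisation by masking: hide a random set of known
# genotypes, impute them at candidate parameter values, and maximize the
# fraction recovered exactly. One fixed mask is shared by every candidate
# so that parameter values are compared on identical problems.

#' Draw a random mask over known genotypes
#'
#' Samples `n_mask` distinct (sample, SNP) coordinates uniformly without
#' replacement from the non-missing entries of `gm`, recording their true
#' genotypes. Reproducible for a fixed seed.
#'
#' @param gm a [geno_matrix].
#' @param n_mask number of genotypes to mask.
#' @param seed RNG seed.
#' @return an object of class `mask_set`: list with `coords` (n x 2 integer
#'   matrix of sample/SNP indices) and `truth` (integer vector).
#' @export
make_mask <- function(gm, n_mask, seed = 1) {
  known <- which(!is.na(gm$dosage))
  if (length(known) < n_mask)
    stop(sprintf("cannot mask %d genotypes: only %d known entries",
                 n_mask, length(known)))
  sel <- withr::with_seed(seed, sample(known, n_mask))
  coords <- arrayInd(sel, dim(gm$dosage))
  structure(list(coords = coords, truth = gm$dosage[coords]),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("mask_set: %d masked genotypes\n", nrow(x$coords)))
  invisible(x)
}

#' Apply a mask: set the masked coordinates to missing
#'
#' @param gm a [geno_matrix].
#' @param mask a [make_mask()] result.
#' @return the masked [geno_matrix].
#' @export
apply_mask <- function(gm, mask) {
  d <- gm$dosage
  d[mask$coords] <- NA_integer_
  geno_matrix(d, chrom = gm$chrom, pos = gm$pos)
}

#' Imputation accuracy at given parameters under a fixed mask
#'
#' Masks all coordinates simultaneously, rebuilds the LD index on the
#' masked matrix (masked entries are missing for LD too -- no leakage of
#' the hidden truth), imputes the masked coordinates, and returns the
#' proportion recovered exactly.
#'
#' @param gm a [geno_matrix] (the unmasked data).
#' @param mask a [make_mask()] result.
#' @param method `"mode"`, `"knni"` or `"ldknni"`.
#' @param k,l,c engine parameters (see [impute_genotypes()]).
#' @param r2 optional precomputed [ld_r2_matrix()] of the MASKED matrix,
#'   shared across calls by the tuner.
#' @return fraction in \[0, 1\].
#' @export
accuracy_at <- function(gm, mask, method = "ldknni", k = NULL, l = NULL,
                        c = 1, r2 = NULL) {
  masked <- apply_mask(gm, mask)
  index <- NULL
  if (method == "ldknni") {
    ll <- if (is.null(l)) 20 else l
    index <- build_ld_index(masked, ll, r2 = r2)
  }
  pred <- .predict_at(masked, mask$coords, method, k = k, l = l, c = c,
                      index = index)
  mean(pred == mask$truth)
}

# Memoized 1-D maximization of f over the integers [lo, hi], assuming a
# unimodal profile: geometric bracketing by doubling from lo until the
# value drops, then integer ternary search inside the bracket. `evals` is
# an environment caching f by key, shared across sweeps.
.search_1d <- function(f, lo, hi) {
  stopifnot(lo <= hi)
  xs <- lo
  while (utils::tail(xs, 1L) < hi) {
    nxt <- min(max(2L * utils::tail(xs, 1L), lo + 1L), hi)
    xs <- c(xs, nxt)
    n <- length(xs)
    if (n >= 2L && f(xs[n]) < f(xs[n - 1L])) break
  }
  n <- length(xs)
  blo <- if (n >= 3L) xs[n - 2L] else xs[1L]
  bhi <- xs[n]
  while (bhi - blo > 2L) {
    m1 <- blo + (bhi - blo) %/% 3L
    m2 <- bhi - (bhi - blo) %/% 3L
    if (m1 == m2) m2 <- m1 + 1L
    if (f(m1) < f(m2)) blo <- m1 + 1L else bhi <- m2 - 1L
  }
  cand <- blo:bhi
  vals <- vapply(cand, f, numeric(1))
  cand[which.max(vals)]
}

#' Optimize imputation parameters on a tuning mask
#'
#' Draws one mask of `n_mask` known genotypes (capped at 10% of the known
#' entries so the tuning problem does not swamp the data with extra
#' missingness) and maximizes exact-recovery accuracy over the integer
#' parameter space, assuming the accuracy surface is unimodal in each
#' coordinate. For `"ldknni"` the search alternates 1-D searches over k
#' and l (each: doubling from the lower bound until accuracy drops, then
#' integer ternary search) until neither changes, for at most `max_sweeps`
#' sweeps; for `"knni"` a single 1-D search over k. The package defaults
#' (k = 5, l = 20 for ldknni; k = 8 for knni) are always evaluated first,
#' so the returned parameters can never score below them on the tuning
#' mask. Every evaluation reuses the same mask and the same LD matrix of
#' the masked data.
#'
#' @param gm a [geno_matrix].
#' @param method `"ldknni"` or `"knni"`.
#' @param n_mask tuning-mask size (default 10000, capped at 10% of known
#'   genotypes; at least 100 after capping).
#' @param k_bounds,l_bounds inclusive integer search ranges (defaults
#'   1..50 and 1..200).
#' @param c LD-kNNi distance constant.
#' @param seed RNG seed for the mask.
#' @param max_sweeps maximum alternating sweeps (default 10).
#' @return list with `k`, `l` (`NA` for knni), `accuracy`, `mask`, and
#'   `trace` (data.frame of every evaluation: k, l, accuracy, in
#'   evaluation order).
#' @export
tune_params <- function(gm, method = c("ldknni", "knni"), n_mask = 10000,
                        k_bounds = c(1L, 50L), l_bounds = c(1L, 200L),
                        c = 1, seed = 1, max_sweeps = 10L) {
  method <- match.arg(method)
  stopifnot(length(k_bounds) == 2L, k_bounds[1L] >= 1,
            k_bounds[1L] <= k_bounds[2L])
  known <- sum(!is.na(gm$dosage))
  n_mask <- min(n_mask, floor(known * 0.10))
  if (n_mask < 100)
    stop("tuning needs at least 100 maskable genotypes (10% of known); have ",
         n_mask)
  mask <- make_mask(gm, n_mask, seed)
  masked <- apply_mask(gm, mask)
  r2 <- if (method == "ldknni") ld_r2_matrix(masked) else NULL
  # the l-slicing in the predictor lets one maximal index serve all l
  max_l <- min(l_bounds[2L], n_snps(gm) - 1L)
  index <- if (method == "ldknni") build_ld_index(masked, max_l, r2 = r2)
  cache <- new.env(parent = emptyenv())
  trace <- list()
  f <- function(k, l) {
    key <- paste(k, l)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pred <- .predict_at(masked, mask$coords, method, k = k, l = l, c = c,
                        index = index)
    acc <- mean(pred == mask$truth)
    cache[[key]] <- acc
    trace[[length(trace) + 1L]] <<- data.frame(k = k, l = if (is.null(l)) NA else l,
                                               accuracy = acc)
    acc
  }
  if (method == "knni") {
    f(8L, NULL)                                  # seed the default
    k_opt <- .search_1d(function(k) f(k, NULL), k_bounds[1L],
                        min(k_bounds[2L], n_samples(gm) - 1L))
    l_opt <- NA_integer_
  } else {
    stopifnot(length(l_bounds) == 2L, l_bounds[1L] >= 1,
              l_bounds[1L] <= l_bounds[2L])
    k_hi <- min(k_bounds[2L], n_samples(gm) - 1L)
    l_hi <- max_l
    k_opt <- max(k_bounds[1L], min(5L, k_hi))    # start from the defaults
    l_opt <- max(l_bounds[1L], min(20L, l_hi))
    f(k_opt, l_opt)
    for (sweep in seq_len(max_sweeps)) {
      k_new <- .search_1d(function(k) f(k, l_opt), k_bounds[1L], k_hi)
      l_new <- .search_1d(function(l) f(k_new, l), l_bounds[1L], l_hi)
      if (k_new == k_opt && l_new == l_opt) break
      k_opt <- k_new
      l_opt <- l_new
    }
  }
  trace <- do.call(rbind, trace)
  best <- trace[which.max(trace$accuracy), ]     # best visited, ties: earliest
  list(k = as.integer(best$k), l = if (method == "knni") NA_integer_ else
         as.integer(best$l),
       accuracy = best$accuracy, mask = mask, trace = trace)
}
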