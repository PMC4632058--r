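# Naive quadratic-time reference implementations, written as plainly as
# possible (explicit loops, base cor()) and kept independent of the
# package's vectorised code paths. They encode the same documented tie
# rules: nearest-neighbour ties by ascending sample index, vote ties to
# the smallest genotype code, zero-distance neighbours (genome-wide
# metric only) vote unweighted.

oracle_vote <- function(genos, dists) {
  if (any(dists == 0)) {
    g <- genos[dists == 0]
    counts <- sapply(0:2, function(a) sum(g == a))
    return(which.max(counts) - 1L)
  }
  scores <- sapply(0:2, function(a) sum(1 / dists[genos == a]))
  which.max(scores) - 1L
}

oracle_mode_value <- function(col) {
  counts <- sapply(0:2, function(a) sum(col == a, na.rm = TRUE))
  which.max(counts) - 1L
}

oracle_mode <- function(G) {
  for (j in seq_len(ncol(G))) {
    miss <- which(is.na(G[, j]))
    if (length(miss)) G[miss, j] <- oracle_mode_value(G[, j])
  }
  G
}

oracle_taxicab <- function(G, s1, s2, snps = seq_len(ncol(G))) {
  tot <- 0; n <- 0L
  for (p in snps) {
    a <- G[s1, p]; b <- G[s2, p]
    if (!is.na(a) && !is.na(b)) {
      tot <- tot + abs(a - b)
      n <- n + 1L
    }
  }
  if (n == 0L) return(list(d = NaN, n = 0L))
  list(d = tot / n, n = n)
}

oracle_knni <- function(G, k) {
  out <- G
  for (s in seq_len(nrow(G))) for (p in seq_len(ncol(G))) {
    if (!is.na(G[s, p])) next
    cand <- c(); dist <- c()
    for (t in seq_len(nrow(G))) {
      if (t == s || is.na(G[t, p])) next
      d <- oracle_taxicab(G, s, t)
      if (d$n == 0L) next
      cand <- c(cand, t); dist <- c(dist, d$d)
    }
    if (length(cand) == 0L) {
      out[s, p] <- oracle_mode_value(G[, p])
      next
    }
    sel <- order(dist, cand)[seq_len(min(k, length(cand)))]
    out[s, p] <- oracle_vote(G[cand[sel], p], dist[sel])
  }
  out
}

# all-pairs r2 by base cor() over pairwise-complete samples
oracle_r2 <- function(G, i, j, min_overlap = 2L) {
  x <- G[, i]; y <- G[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_overlap) return(0)
  if (length(unique(x[ok])) < 2L || length(unique(y[ok])) < 2L) return(0)
  cor(x[ok], y[ok])^2
}

oracle_ld_index <- function(G, l) {
  # ranks rounded r2 (ties at 1e-12 break by SNP index), mirroring the
  # documented deterministic tie rule
  m <- ncol(G)
  lapply(seq_len(m), function(p) {
    r2 <- sapply(seq_len(m), function(q) if (q == p) -Inf else
      round(oracle_r2(G, p, q), 12))
    order(-r2, seq_len(m))[seq_len(min(l, m - 1L))]
  })
}

oracle_ldknni <- function(G, k, l, cc = 1) {
  idx <- oracle_ld_index(G, l)
  out <- G
  for (s in seq_len(nrow(G))) for (p in seq_len(ncol(G))) {
    if (!is.na(G[s, p])) next
    Lp <- idx[[p]]
    cand <- c(); dist <- c()
    for (t in seq_len(nrow(G))) {
      if (t == s || is.na(G[t, p])) next
      d <- oracle_taxicab(G, s, t, snps = Lp)
      dd <- if (d$n == 0L) cc else cc + d$d
      cand <- c(cand, t); dist <- c(dist, dd)
    }
    if (length(cand) == 0L) {
      out[s, p] <- oracle_mode_value(G[, p])
      next
    }
    sel <- order(dist, cand)[seq_len(min(k, length(cand)))]
    out[s, p] <- oracle_vote(G[cand[sel], p], dist[sel])
  }
  out
}

# exact heterozygote-excess p-value by brute enumeration of genotype
# configurations with the observed allele counts
oracle_hwe_excess <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  na_ <- 2 * n2 + n1
  if (na_ == 0 || 2 * n - na_ == 0) return(NA_real_)
  hets <- seq(na_ %% 2, min(na_, 2 * n - na_), by = 2)
  pr <- sapply(hets, function(h) {
    h2 <- (na_ - h) / 2
    h0 <- n - h - h2
    exp(lfactorial(n) - lfactorial(h0) - lfactorial(h) - lfactorial(h2) +
          h * log(2) + lfactorial(na_) + lfactorial(2 * n - na_) -
          lfactorial(2 * n))
  })
  sum(pr[hets >= n1]) / sum(pr)
}
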