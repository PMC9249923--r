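# Small builders shared across test files. All fixtures are generated in
# code; no data files.

# count_matrix with explicit counts and equal library sizes
toy_counts <- function(counts, group, libsize = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  count_matrix(counts, group, libsize)
}

# de_result from explicit columns
toy_de <- function(ids, logFC, FDR, contrast, PValue = FDR) {
  res <- data.frame(transcript_id = ids, logFC = logFC, PValue = PValue,
                    FDR = FDR)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

# random de_result triple over a shared namespace (for property tests)
random_de_triple <- function(n = 60, fractions = c("A", "B", "C")) {
  ids <- sprintf("t%03d", seq_len(n))
  mk <- function(ct) toy_de(ids, logFC = rnorm(n), FDR = runif(n), ct)
  list(mk(fractions[c(1, 2)]), mk(fractions[c(1, 3)]),
       mk(fractions[c(2, 3)]))
}

# independent step-by-step TMM re-derivation (spreadsheet-style oracle)
oracle_tmm_pair <- function(y, n, yr, nr, lt = 0.3, st = 0.05) {
  ok <- y > 0 & yr > 0
  y <- y[ok]; yr <- yr[ok]
  M <- log2((y / n) / (yr / nr))
  A <- 0.5 * log2((y / n) * (yr / nr))
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  k <- length(M)
  keepM <- rank(M) >= floor(k * lt) + 1 & rank(M) <= k - floor(k * lt)
  keepA <- rank(A) >= floor(k * st) + 1 & rank(A) <= k - floor(k * st)
  keep <- keepM & keepA
  2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
}

# independent doubletail oracle: split distribution built by explicit
# convolution of per-replicate NB (or Poisson) mass functions
oracle_doubletail <- function(za, zb, na, nb, phi, tol = 1e-12) {
  z <- za + zb
  if (z == 0) return(1)
  m <- z / (na + nb)
  pmf1 <- if (phi == 0) dpois(0:z, m) else
    dnbinom(0:z, size = 1 / phi, mu = m)
  conv_n <- function(p, n) {
    out <- p
    if (n > 1) for (i in 2:n) {
      new <- numeric(z + 1)
      for (k in 0:z)
        new[k + 1] <- sum(out[seq_len(k + 1)] * p[(k + 1):1])
      out <- new
    }
    out
  }
  pa <- conv_n(pmf1, na)
  pb <- conv_n(pmf1, nb)
  pr <- pa[1:(z + 1)] * pb[(z + 1):1]
  obs <- pr[za + 1]
  sum(pr[pr <= obs * (1 + tol)]) / sum(pr)
}

# brute-force Benjamini-Hochberg (independent of stats::p.adjust)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# independent hypergeometric upper tail via explicit choose() sums
oracle_hyper_tail <- function(a, nA, nB, N) {
  ks <- a:min(nA, nB)
  sum(choose(nA, ks) * choose(N - nA, nB - ks)) / choose(N, nB)
}
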