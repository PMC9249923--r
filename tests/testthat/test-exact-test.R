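test_that("BH adjustment matches brute-force step-up and its edge cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "finite")
  expect_error(bh_adjust(c(0.1, 1.2)), "within")
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)
    fdr <- bh_adjust(p)
    expect_equal(fdr, oracle_bh(p))
    expect_true(all(fdr >= p))
    expect_true(all(diff(fdr[order(p)]) >= -1e-12))
  }
})

test_that("identical group counts give p = 1", {
  x <- toy_counts(matrix(3, 1, 4), c("a", "a", "b", "b"),
                  libsize = rep(100, 4))
  de <- nb_exact_test(x, dispersion = 0.2, contrast = c("a", "b"))
  expect_equal(de$PValue, 1)
  expect_equal(de$logFC, 0, tolerance = 1e-12)
})

test_that("doubletail p equals independent convolution enumeration", {
  # all group-sum splits with totals z <= 12, n = 2+2, several dispersions
  for (phi in c(0, 0.1, 0.5)) {
    for (z in c(1, 5, 12)) {
      for (za in 0:z) {
        zb <- z - za
        counts <- matrix(c(floor(za / 2), ceiling(za / 2),
                           floor(zb / 2), ceiling(zb / 2)), 1)
        x <- toy_counts(counts, c("a", "a", "b", "b"),
                        libsize = rep(50, 4))
        de <- nb_exact_test(x, dispersion = max(phi, 1e-12),
                            contrast = c("a", "b"))
        expect_equal(de$PValue, oracle_doubletail(za, zb, 2, 2, phi),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the Poisson limit reduces to the conditional binomial test", {
  # equal library sizes: splits are Binomial(z, nA / (nA + nB))
  za <- 21; zb <- 3
  x <- toy_counts(matrix(c(7, 7, 7, 1, 1, 1), 1), rep(c("a", "b"), each = 3),
                  libsize = rep(80, 6))
  de <- nb_exact_test(x, dispersion = 1e-14, contrast = c("a", "b"))
  z <- za + zb
  pr <- dbinom(0:z, z, 0.5)
  expect_equal(de$PValue,
               sum(pr[pr <= pr[za + 1] * (1 + 1e-12)]),
               tolerance = 1e-12)
})

test_that("all-zero transcripts get p = 1 and logFC = 0", {
  x <- toy_counts(rbind(c(0, 0, 0, 0), c(9, 9, 2, 2)),
                  c("a", "a", "b", "b"), libsize = rep(100, 4))
  de <- nb_exact_test(x, dispersion = 0.1, contrast = c("a", "b"))
  expect_equal(de$PValue[1], 1)
  expect_equal(de$logFC[1], 0)
})

test_that("swapping the contrast negates logFC and preserves p", {
  set.seed(5)
  counts <- matrix(rnbinom(100 * 6, mu = 50, size = 10), 100, 6)
  x <- toy_counts(counts, rep(c("a", "b"), each = 3),
                  libsize = rep(5000, 6))
  d1 <- nb_exact_test(x, dispersion = 0.1, contrast = c("a", "b"))
  d2 <- nb_exact_test(x, dispersion = 0.1, contrast = c("b", "a"))
  expect_equal(d1$PValue, d2$PValue)
  expect_equal(d1$logFC, -d2$logFC, tolerance = 1e-12)
})

test_that("the exact test agrees with edgeR on equal library sizes", {
  set.seed(6)
  counts <- matrix(rnbinom(200 * 4, mu = 60, size = 5), 200, 4)
  grp <- c("a", "a", "b", "b")
  x <- toy_counts(counts, grp, libsize = rep(12000, 4))
  de <- nb_exact_test(x, dispersion = 0.2, contrast = c("b", "a"))
  dg <- edgeR::DGEList(counts, group = factor(grp), lib.size = rep(12000, 4))
  et <- edgeR::exactTest(dg, pair = c("a", "b"), dispersion = 0.2)
  expect_equal(de$PValue, et$table$PValue, tolerance = 1e-6)
})

test_that("p-values are insensitive to rescaling a sample with its libsize", {
  set.seed(8)
  counts <- matrix(rnbinom(150 * 6, mu = 100, size = 20), 150, 6)
  lib <- rep(1.5e4, 6)
  x1 <- toy_counts(counts, rep(c("a", "b"), each = 3), libsize = lib)
  counts2 <- counts; counts2[, 1] <- counts2[, 1] * 4
  lib2 <- lib * c(4, 1, 1, 1, 1, 1)
  x2 <- toy_counts(counts2, rep(c("a", "b"), each = 3), libsize = lib2)
  p1 <- nb_exact_test(x1, 0.1, contrast = c("a", "b"))$PValue
  p2 <- nb_exact_test(x2, 0.1, contrast = c("a", "b"))$PValue
  # equalization rounds pseudo-counts, so agreement is near-exact, not exact
  expect_gt(cor(p1, p2, method = "spearman"), 0.99)
  expect_lt(max(abs(p1 - p2)), 0.02)
})
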