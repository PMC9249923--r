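#' Trimmed mean of M-values normalization factors
#'
#' Computes between-sample scaling factors by the TMM method: for each sample
#' against a reference, per-transcript log2 expression ratios (M) and average
#' log2 abundances (A) are formed over transcripts nonzero in both samples;
#' the most extreme 30% of M values and 5% of A values are discarded; the
#' factor is 2 to the precision-weighted mean of the surviving M values, with
#' weights the asymptotic binomial (delta-method) variances. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param x A filtered `count_matrix` with at least two samples.
#' @param ref_sample Reference sample name or index; by default the sample
#'   whose upper-quartile CPM is closest to the mean upper quartile.
#' @param logratio_trim Fraction of M values trimmed at each extreme
#'   (default 0.3).
#' @param sum_trim Fraction of A values trimmed at each extreme
#'   (default 0.05).
#' @return Object of class `tmm_norm`: list with `tmm_factor`,
#'   `effective_libsize` (= libsize x factor) and `ref_sample`.
#' @export
tmm_factors <- function(x, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  stopifnot(inherits(x, "count_matrix"))
  counts <- x$counts
  lib <- x$samples$libsize
  nsamp <- ncol(counts)
  if (nsamp < 2) stop("TMM needs at least two samples")
  if (is.null(ref_sample)) {
    uq <- apply(cpm(x), 2, stats::quantile, probs = 0.75)
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref_sample)) {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample")
  } else ref <- as.integer(ref_sample)

  f <- vapply(seq_len(nsamp), function(k) {
    if (k == ref) return(1)
    .tmm_pair(counts[, k], lib[k], counts[, ref], lib[ref],
              logratio_trim, sum_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(tmm_factor = f,
                 effective_libsize = lib * f,
                 ref_sample = colnames(counts)[ref]),
            class = "tmm_norm")
}

# One sample vs reference; edgeR-convention double trim on M and A ranks.
.tmm_pair <- function(y, n, yr, nr, logratio_trim, sum_trim) {
  ok <- y > 0 & yr > 0
  if (!any(ok)) stop("sample shares no expressed transcripts with reference")
  y <- y[ok]; yr <- yr[ok]
  p <- y / n; pr <- yr / nr
  M <- log2(p / pr)
  A <- (log2(p) + log2(pr)) / 2
  w <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (max(abs(M)) < 1e-6) return(1)
  nk <- length(M)
  loM <- floor(nk * logratio_trim) + 1; hiM <- nk + 1 - loM
  loA <- floor(nk * sum_trim) + 1;      hiA <- nk + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' @export
print.tmm_norm <- function(x, ...) {
  cat("TMM normalization (reference:", x$ref_sample, ")\n")
  print(round(x$tmm_factor, 4))
  invisible(x)
}
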