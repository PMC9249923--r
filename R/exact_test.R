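#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust]).
#'
#' @param p Numeric vector of p-values in \[0, 1\]; `NA`/`NaN` not allowed.
#' @return Vector of FDR-adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must be finite and within [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pairwise negative-binomial exact test
#'
#' Two-group doubletail exact test for count data. Counts are equalized to a
#' common library size (deterministic scaling pseudo-counts); conditional on
#' the total z of a transcript across both groups, the group sums follow
#' NB(n_A * m, phi / n_A) and NB(n_B * m, phi / n_B) with m = z / (n_A + n_B).
#' The p-value sums the probabilities of every split of z no more probable
#' than the observed one (relative tie tolerance 1e-12). In the phi -> 0
#' limit the split distribution is binomial and that exact form is used.
#'
#' log2 fold changes are computed from group-average CPM on the equalized
#' counts with a prior of 0.5 CPM: log2((cpmA + 0.5) / (cpmB + 0.5)).
#' FDR is controlled with [bh_adjust].
#'
#' @param x A filtered `count_matrix`.
#' @param dispersion Scalar or per-transcript dispersion vector (from
#'   [estimate_tagwise_dispersion] or a known value).
#' @param norm Optional `tmm_norm` for effective library sizes.
#' @param contrast Character vector `c(A, B)`: log2FC is A over B. Defaults
#'   to the first two group levels.
#' @param prior_count Prior CPM added to both group averages (default 0.5).
#' @return Object of class `de_result`: data frame with columns
#'   `transcript_id`, `logFC`, `PValue`, `FDR` and an attribute `contrast`.
#' @export
nb_exact_test <- function(x, dispersion, norm = NULL, contrast = NULL,
                          prior_count = 0.5) {
  stopifnot(inherits(x, "count_matrix"))
  group <- x$samples$group
  if (is.null(contrast)) contrast <- unique(group)[1:2]
  if (length(contrast) != 2 || !all(contrast %in% group))
    stop("contrast must name two groups present in the data")
  sel <- group %in% contrast
  counts <- x$counts[, sel, drop = FALSE]
  group <- group[sel]
  lib <- if (is.null(norm)) x$samples$libsize[sel]
         else norm$effective_libsize[sel]
  eq <- equalize_counts(counts, lib)
  pseudo <- eq$pseudo
  ia <- group == contrast[1]
  ib <- group == contrast[2]
  na <- sum(ia); nb <- sum(ib)
  za <- rowSums(pseudo[, ia, drop = FALSE])
  zb <- rowSums(pseudo[, ib, drop = FALSE])
  G <- nrow(pseudo)
  phi <- rep_len(dispersion, G)

  p <- vapply(seq_len(G), function(i)
    .doubletail_p(za[i], zb[i], na, nb, phi[i]), numeric(1))

  cpma <- za / na / eq$nstar * 1e6
  cpmb <- zb / nb / eq$nstar * 1e6
  logFC <- log2((cpma + prior_count) / (cpmb + prior_count))
  logFC[za + zb == 0] <- 0

  res <- data.frame(transcript_id = rownames(pseudo), logFC = logFC,
                    PValue = p, FDR = bh_adjust(p), row.names = NULL)
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}

# Doubletail p-value for one transcript: enumerate all splits of z = za + zb.
.doubletail_p <- function(za, zb, na, nb, phi, tol = 1e-12) {
  z <- za + zb
  if (z == 0) return(1)
  k <- 0:z
  if (phi < 1e-10) {
    lp <- stats::dbinom(k, z, na / (na + nb), log = TRUE)
  } else {
    m <- z / (na + nb)
    lp <- stats::dnbinom(k, size = na / phi, mu = na * m, log = TRUE) +
      stats::dnbinom(z - k, size = nb / phi, mu = nb * m, log = TRUE)
  }
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  tot <- sum(pr)
  obs <- pr[za + 1]
  min(1, sum(pr[pr <= obs * (1 + tol)]) / tot)
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("NB exact test:", ct[1], "vs", ct[2], "-", nrow(x), "transcripts,",
      sum(x$FDR < 0.05), "at FDR < 0.05\n")
  print.data.frame(utils::head(x[order(x$PValue), ], 6), row.names = FALSE)
  invisible(x)
}

#' Write a differential-expression table as TSV
#'
#' Columns `transcript_id`, `logFC`, `PValue`, `FDR`, matching the layout of
#' edgeR-style supplementary DE tables so externally produced files can be
#' read back with [read_de_table].
#'
#' @param de A `de_result`.
#' @param path Output path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(as.data.frame(de), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_table
#' @param contrast Contrast label `c(A, B)` to attach on read.
#' @export
read_de_table <- function(path, contrast = NULL) {
  res <- utils::read.delim(path)
  stopifnot(all(c("transcript_id", "logFC", "PValue", "FDR") %in% names(res)))
  attr(res, "contrast") <- contrast
  class(res) <- c("de_result", "data.frame")
  res
}
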