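#' @keywords internal
#' Equalize counts to a common library size.
#'
#' Deterministic scaling pseudo-counts: y' = round(y * N* / L_eff) with
#' banker's (half-even) rounding, where N* is the geometric mean of the
#' effective library sizes. After equalization all samples share library
#' size N*, which the conditional-likelihood machinery assumes.
equalize_counts <- function(counts, effective_libsize) {
  nstar <- exp(mean(log(effective_libsize)))
  pseudo <- round(sweep(counts, 2, nstar / effective_libsize, "*"))
  list(pseudo = pseudo, nstar = nstar)
}

# Conditional log-likelihood of phi for one group's equalized counts,
# conditioning on the per-transcript group total (the NB mean drops out).
# y: matrix (transcripts x replicates), returns vector over transcripts.
.cond_ll_group <- function(y, phi) {
  n <- ncol(y)
  r <- 1 / phi
  z <- rowSums(y)
  rowSums(lgamma(y + r)) - n * lgamma(r) + lgamma(n * r) - lgamma(z + n * r)
}

# Summed conditional log-likelihood across groups with replication.
# Returns a transcripts-long vector for scalar phi.
.cond_ll <- function(counts, group, phi) {
  ll <- numeric(nrow(counts))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) >= 2)
      ll <- ll + .cond_ll_group(counts[, idx, drop = FALSE], phi)
  }
  ll
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Counts are first equalized to a common library size (see the package
#' vignette); the dispersion maximizing the conditional log-likelihood summed
#' over transcripts and replicated groups is then found by bounded search on
#' log10(phi) in \[-6, 2\]. The NB parameterization is
#' variance = mean + phi * mean^2.
#'
#' @param x A filtered `count_matrix`.
#' @param norm Optional `tmm_norm`; effective library sizes are used when
#'   supplied, raw library sizes otherwise.
#' @return Scalar dispersion estimate.
#' @export
estimate_common_dispersion <- function(x, norm = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- if (is.null(norm)) x$samples$libsize else norm$effective_libsize
  group <- x$samples$group
  if (!any(table(group) >= 2))
    stop("no replicated group: supply a fixed dispersion instead")
  pseudo <- equalize_counts(x$counts, lib)$pseudo
  opt <- stats::optimize(function(l10) sum(.cond_ll(pseudo, group, 10^l10)),
                         interval = c(-6, 2), maximum = TRUE, tol = 1e-8)
  10^opt$maximum
}

#' Tagwise dispersions with shrinkage toward the common likelihood
#'
#' Per transcript, maximizes l_g(phi) + prior_weight * lbar(phi), where lbar
#' is the average conditional log-likelihood over all transcripts. The
#' default prior weight corresponds to about 10 prior degrees of freedom:
#' prior_df / (n_samples - n_groups). Maximization is over a log10 grid on
#' \[-6, 2\] with quadratic interpolation around the grid maximum.
#'
#' @inheritParams estimate_common_dispersion
#' @param prior_df Prior degrees of freedom for shrinkage (default 10).
#' @param prior_weight Weight on the average likelihood; overrides
#'   `prior_df` when given. `Inf` collapses all estimates onto the common
#'   maximizer; 0 gives per-transcript conditional MLEs.
#' @param grid_length Number of grid points (default 81).
#' @return Numeric vector of per-transcript dispersions.
#' @export
estimate_tagwise_dispersion <- function(x, norm = NULL, prior_df = 10,
                                        prior_weight = NULL,
                                        grid_length = 81) {
  stopifnot(inherits(x, "count_matrix"))
  lib <- if (is.null(norm)) x$samples$libsize else norm$effective_libsize
  group <- x$samples$group
  if (!any(table(group) >= 2))
    stop("no replicated group: supply a fixed dispersion instead")
  pseudo <- equalize_counts(x$counts, lib)$pseudo
  df_resid <- ncol(pseudo) - length(unique(group))
  if (is.null(prior_weight))
    prior_weight <- if (df_resid > 0) prior_df / df_resid else prior_df
  grid <- seq(-6, 2, length.out = grid_length)
  L <- vapply(grid, function(l10) .cond_ll(pseudo, group, 10^l10),
              numeric(nrow(pseudo)))            # transcripts x grid
  lbar <- colMeans(L)
  S <- if (is.infinite(prior_weight))
    matrix(lbar, nrow(L), length(grid), byrow = TRUE)
  else
    L + matrix(prior_weight * lbar, nrow(L), length(grid), byrow = TRUE)
  best <- max.col(S, ties.method = "first")
  # quadratic interpolation on log10 phi around the grid maximum
  l10 <- vapply(seq_len(nrow(S)), function(i) {
    j <- best[i]
    if (j == 1 || j == length(grid)) return(grid[j])
    y0 <- S[i, j - 1]; y1 <- S[i, j]; y2 <- S[i, j + 1]
    den <- y0 - 2 * y1 + y2
    if (den >= 0) return(grid[j])
    grid[j] + 0.5 * (y0 - y2) / den * (grid[2] - grid[1])
  }, numeric(1))
  phi <- 10^l10
  names(phi) <- rownames(x$counts)
  phi
}
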