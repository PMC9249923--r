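#' Counts per million
#'
#' @param x A `count_matrix`, or a numeric matrix (then `libsize` is
#'   required).
#' @param libsize Library sizes; defaults to those stored in `x`.
#' @return Matrix of CPM values with the same dimnames as the counts.
#' @export
cpm <- function(x, libsize = NULL) {
  if (inherits(x, "count_matrix")) {
    if (is.null(libsize)) libsize <- x$samples$libsize
    x <- x$counts
  }
  if (is.null(libsize)) stop("libsize required for a bare matrix")
  if (any(libsize <= 0)) stop("library sizes must be positive")
  sweep(x, 2, libsize, "/") * 1e6
}

#' Remove lowly expressed transcripts
#'
#' Retains transcripts with CPM at or above `min_cpm` in at least
#' `min_samples` samples, then recomputes library sizes as column sums of the
#' retained matrix. This is the standard pre-filter applied before
#' normalization and dispersion estimation: `min_samples` is usually set to
#' the smallest group size.
#'
#' @param x A `count_matrix`.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples Number of samples that must reach `min_cpm`.
#' @return Filtered `count_matrix` with recomputed library sizes.
#' @export
filter_low_expression <- function(x, min_cpm = 1,
                                  min_samples = min(table(x$samples$group))) {
  stopifnot(inherits(x, "count_matrix"), min_samples >= 1)
  keep <- rowSums(cpm(x) >= min_cpm) >= min_samples
  if (!any(keep)) stop("all transcripts removed by expression filter")
  count_matrix(x$counts[keep, , drop = FALSE], x$samples$group)
}
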