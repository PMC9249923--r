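#' Transcript-by-sample count matrix with sample metadata
#'
#' The substrate of all bulk computation: an integer matrix of transcript
#' counts with per-sample group labels and library sizes. Library sizes
#' default to column sums and are recomputed whenever transcripts are
#' dropped.
#'
#' @param counts Integer matrix, transcripts in rows, samples in columns.
#'   Must have rownames (transcript ids); colnames default to `sample1..n`.
#' @param group Character or factor of length `ncol(counts)`; experimental
#'   group of each sample. At least two levels are required for differential
#'   expression.
#' @param libsize Optional positive numeric vector of library sizes; defaults
#'   to `colSums(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `samples` (data frame with columns `sample`, `group`,
#'   `libsize`).
#' @export
count_matrix <- function(counts, group, libsize = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("t%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop("group must have one label per sample")
  if (is.null(libsize)) libsize <- colSums(counts)
  libsize <- as.numeric(libsize)
  if (length(libsize) != ncol(counts) || any(libsize <= 0))
    stop("libsize must be positive, one value per sample")
  structure(
    list(counts = counts,
         samples = data.frame(sample = colnames(counts), group = group,
                              libsize = libsize, row.names = NULL)),
    class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  cat("library sizes:", paste(format(range(x$samples$libsize), big.mark = ","),
                              collapse = " - "), "\n")
  invisible(x)
}

#' Combine count matrices column-wise
#'
#' Samples are concatenated; all inputs must share the same transcript ids in
#' the same order. Duplicate sample names are made unique.
#'
#' @param ... `count_matrix` objects.
#' @return A `count_matrix`.
#' @export
cbind_counts <- function(...) {
  xs <- list(...)
  ids <- rownames(xs[[1]]$counts)
  for (x in xs)
    if (!identical(rownames(x$counts), ids))
      stop("count matrices do not share a transcript namespace")
  counts <- do.call(cbind, lapply(xs, function(x) x$counts))
  colnames(counts) <- make.unique(colnames(counts))
  group <- unlist(lapply(xs, function(x) x$samples$group), use.names = FALSE)
  libsize <- unlist(lapply(xs, function(x) x$samples$libsize),
                    use.names = FALSE)
  count_matrix(counts, group, libsize)
}

#' Write / read a count matrix as TSV
#'
#' Counts go to `<stem>.counts.tsv` (transcripts x samples, first column
#' `transcript_id`) and sample metadata to `<stem>.samples.tsv` (columns
#' `sample`, `group`, `libsize`).
#'
#' @param x A `count_matrix`.
#' @param stem Path stem for the two files.
#' @return `write_counts` returns the two paths invisibly; `read_counts`
#'   returns a `count_matrix`.
#' @export
write_counts <- function(x, stem) {
  cf <- paste0(stem, ".counts.tsv")
  sf <- paste0(stem, ".samples.tsv")
  df <- data.frame(transcript_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, cf, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, sf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = cf, samples = sf))
}

#' @rdname write_counts
#' @export
read_counts <- function(stem) {
  cf <- paste0(stem, ".counts.tsv")
  sf <- paste0(stem, ".samples.tsv")
  df <- utils::read.delim(cf, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  samples <- utils::read.delim(sf)
  counts <- counts[, samples$sample, drop = FALSE]
  count_matrix(counts, samples$group, samples$libsize)
}
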