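#' Derive fraction signature transcript sets
#'
#' A transcript belongs to fraction f's signature when it is significantly
#' enriched (log2FC > 0, FDR < `fdr_cut`) in f compared to *both* other
#' fractions. The three pairwise `de_result` tables must carry `contrast`
#' attributes; orientation is resolved from them, so input order does not
#' matter. Signatures are pairwise disjoint by construction (a transcript
#' cannot be up in A-vs-B and up in B-vs-A).
#'
#' @param de_ab,de_ac,de_bc `de_result` objects for the three pairwise
#'   contrasts among three fractions, each covering the same transcripts.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return Object of class `signature_set`: list with `scheme` (the three
#'   fraction names), `members` (named list of transcript-id vectors) and
#'   `fdr_cut`.
#' @export
derive_fraction_signatures <- function(de_ab, de_ac, de_bc, fdr_cut = 0.05) {
  des <- list(de_ab, de_ac, de_bc)
  ids <- sort(des[[1]]$transcript_id)
  for (d in des) {
    if (is.null(attr(d, "contrast")))
      stop("each de_result needs a contrast attribute")
    if (!identical(sort(d$transcript_id), ids))
      stop("DE tables do not cover the same transcript universe")
  }
  fractions <- unique(unlist(lapply(des, attr, "contrast")))
  if (length(fractions) != 3)
    stop("expected three fractions across the pairwise contrasts")
  members <- lapply(fractions, function(f) {
    hits <- lapply(des, function(d) {
      ct <- attr(d, "contrast")
      if (ct[1] == f) d$transcript_id[d$logFC > 0 & d$FDR < fdr_cut]
      else if (ct[2] == f) d$transcript_id[d$logFC < 0 & d$FDR < fdr_cut]
      else NULL
    })
    hits <- Filter(Negate(is.null), hits)
    if (length(hits) != 2)
      stop("fraction ", f, " does not appear in exactly two contrasts")
    intersect(hits[[1]], hits[[2]])
  })
  names(members) <- fractions
  structure(list(scheme = fractions, members = members, fdr_cut = fdr_cut),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature_set (FDR <", x$fdr_cut, "):\n")
  for (f in x$scheme)
    cat(" ", f, ":", length(x$members[[f]]), "transcripts\n")
  invisible(x)
}

#' Up/down dysregulated transcript sets for one condition
#'
#' @param de A `de_result`.
#' @param fdr_cut FDR threshold (default 0.05).
#' @param condition Label for the perturbed condition; defaults to the
#'   contrast's first group.
#' @return Object of class `dysregulation_sets`: list with `up`, `down`
#'   (transcript-id vectors) and `condition`.
#' @export
dysregulated_sets <- function(de, fdr_cut = 0.05, condition = NULL) {
  if (is.null(condition))
    condition <- if (!is.null(attr(de, "contrast")))
      attr(de, "contrast")[1] else "condition"
  structure(list(
    up = de$transcript_id[de$logFC > 0 & de$FDR < fdr_cut],
    down = de$transcript_id[de$logFC < 0 & de$FDR < fdr_cut],
    condition = condition), class = "dysregulation_sets")
}

#' @export
print.dysregulation_sets <- function(x, ...) {
  cat("dysregulation_sets [", x$condition, "]: ", length(x$up), " up, ",
      length(x$down), " down\n", sep = "")
  invisible(x)
}

#' Single-cell detection call
#'
#' A transcript is detected when it has nonzero expression in at least
#' `min_cell_frac` of cells — per subcluster when a cell-to-subcluster
#' assignment is given (a transcript detected in *any* subcluster counts as
#' detected), otherwise over all cells.
#'
#' @param mat Sparse or dense matrix, transcripts x cells, with rownames.
#' @param subclusters Optional factor/character of length `ncol(mat)`.
#' @param min_cell_frac Detection threshold as a fraction of cells
#'   (default 0.005, i.e. 0.5%).
#' @return Character vector of detected transcript ids.
#' @export
sc_detected <- function(mat, subclusters = NULL, min_cell_frac = 0.005) {
  if (is.null(rownames(mat))) stop("matrix must have transcript rownames")
  detected_in <- function(cols) {
    m <- mat[, cols, drop = FALSE]
    nz <- if (inherits(m, "sparseMatrix")) Matrix::rowSums(m != 0)
          else rowSums(m != 0)
    nz >= min_cell_frac * length(cols)
  }
  if (is.null(subclusters)) {
    keep <- detected_in(seq_len(ncol(mat)))
  } else {
    stopifnot(length(subclusters) == ncol(mat))
    keep <- Reduce(`|`, lapply(split(seq_along(subclusters), subclusters),
                               detected_in))
  }
  rownames(mat)[keep]
}

#' Conservative detection universe for overlap testing
#'
#' The background ("genome size") for Fisher overlap tests: only transcripts
#' detected in *every* supplied component. Components may be character
#' vectors of detected ids, `count_matrix` objects (detection = surviving
#' [filter_low_expression] with the given thresholds), or matrices with
#' rownames (all rows taken as detected, e.g. an already-filtered matrix).
#'
#' @param ... Components to intersect.
#' @param min_cpm,min_samples Filter settings applied to raw `count_matrix`
#'   components.
#' @return Object of class `universe_set`: list with `members` and
#'   `n_components`.
#' @export
detected_universe <- function(..., min_cpm = 1, min_samples = NULL) {
  comps <- list(...)
  if (!length(comps)) stop("no components supplied")
  dets <- lapply(comps, function(cc) {
    if (is.character(cc)) cc
    else if (inherits(cc, "count_matrix")) {
      ms <- if (is.null(min_samples)) min(table(cc$samples$group))
            else min_samples
      rownames(filter_low_expression(cc, min_cpm, ms)$counts)
    } else if (!is.null(rownames(cc))) rownames(cc)
    else stop("unsupported universe component")
  })
  members <- Reduce(intersect, dets)
  if (!length(members))
    stop("empty detection universe: transcript namespaces do not overlap")
  structure(list(members = members, n_components = length(dets)),
            class = "universe_set")
}

#' @export
print.universe_set <- function(x, ...) {
  cat("universe_set:", length(x$members), "transcripts detected in",
      x$n_components, "components\n")
  invisible(x)
}

#' Serialize transcript sets as TSV
#'
#' Signature and dysregulation sets are written as two-column TSV
#' (`set_name`, `transcript_id`); universes as a one-column TSV.
#'
#' @param x A `signature_set`, `dysregulation_sets` or `universe_set`.
#' @param path Output path.
#' @export
write_sets <- function(x, path) {
  if (inherits(x, "universe_set")) {
    utils::write.table(data.frame(transcript_id = x$members), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    sets <- if (inherits(x, "signature_set")) x$members
            else list(up = x$up, down = x$down)
    df <- data.frame(
      set_name = rep(names(sets), lengths(sets)),
      transcript_id = unlist(sets, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
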