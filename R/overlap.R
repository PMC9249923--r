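#' Fisher overlap test over an explicit universe
#'
#' Tests whether two transcript sets overlap more than expected by chance
#' within a declared background universe. The one-sided (enrichment) p-value
#' is the upper hypergeometric tail of the observed intersection size; a
#' two-sided alternative delegates to [stats::fisher.test]. Both sets must
#' be contained in the universe (the conservative-universe rule).
#'
#' @param setA,setB Character vectors of transcript ids.
#' @param universe Character vector or `universe_set`.
#' @param alternative `"greater"` (default, enrichment) or `"two.sided"`.
#' @return Object of class `overlap_result`: list with the 2x2 cells `a`
#'   (overlap), `b` (A only), `c` (B only), `d` (neither), `p_value` and the
#'   sample cross-product `odds_ratio` (`Inf` when `b * c == 0`).
#' @export
fisher_overlap <- function(setA, setB, universe,
                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(universe, "universe_set")) universe <- universe$members
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be contained in the universe")
  a <- length(intersect(setA, setB))
  b <- length(setA) - a
  c_ <- length(setB) - a
  d <- length(universe) - a - b - c_
  p <- if (alternative == "greater") {
    # P(overlap >= a) drawing |B| from a universe with |A| marked
    stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  } else {
    stats::fisher.test(matrix(c(a, b, c_, d), 2), alternative = "two.sided")$p.value
  }
  or <- if (b * c_ == 0) Inf else (a * d) / (b * c_)
  structure(list(a = a, b = b, c = c_, d = d,
                 p_value = min(1, p), odds_ratio = or,
                 alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap:", x$a, "| A-only:", x$b, "| B-only:", x$c,
      "| neither:", x$d, "\n")
  cat("Fisher p (", x$alternative, "): ", format(x$p_value, digits = 4),
      ", odds ratio: ", format(x$odds_ratio, digits = 4), "\n", sep = "")
  invisible(x)
}

# Shared engine for the two dysregulation profiles: named list of
# denominator sets vs one dysregulation_sets object.
.dysreg_profile <- function(sets, dysreg, universe, alternative) {
  if (inherits(universe, "universe_set")) universe <- universe$members
  up <- intersect(dysreg$up, universe)
  down <- intersect(dysreg$down, universe)
  any_dys <- union(up, down)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (!all(s %in% universe))
      stop("set '", nm, "' is not contained in the universe")
    n <- length(s)
    if (n == 0) {
      warning("empty set '", nm, "': percentages undefined")
      return(data.frame(set = nm, n_set = 0L, n_up = NA_integer_,
                        n_down = NA_integer_, pct_up = NA_real_,
                        pct_down = NA_real_, fisher_p = NA_real_,
                        odds_ratio = NA_real_))
    }
    nu <- length(intersect(s, up))
    nd <- length(intersect(s, down))
    ov <- fisher_overlap(s, any_dys, universe, alternative)
    data.frame(set = nm, n_set = n, n_up = nu, n_down = nd,
               pct_up = 100 * nu / n, pct_down = 100 * nd / n,
               fisher_p = ov$p_value, odds_ratio = ov$odds_ratio)
  })
  do.call(rbind, rows)
}

#' Percentage of signature transcripts dysregulated in a condition
#'
#' For each fraction signature, reports the percentage of its transcripts
#' up- and downregulated in the perturbed condition (overlap count divided by
#' signature size) and a Fisher overlap test of the signature against the
#' union of up- and downregulated sets, all within the supplied universe.
#'
#' @param signatures A `signature_set`.
#' @param dysreg A `dysregulation_sets`.
#' @param universe Character vector or `universe_set` containing all sets.
#' @param alternative Passed to [fisher_overlap].
#' @return Data frame with one row per fraction: `set`, `n_set`, `n_up`,
#'   `n_down`, `pct_up`, `pct_down`, `fisher_p`, `odds_ratio`.
#' @export
signature_dysregulation_profile <- function(signatures, dysreg, universe,
                                            alternative = "greater") {
  stopifnot(inherits(signatures, "signature_set"))
  if (inherits(universe, "universe_set")) universe <- universe$members
  sets <- lapply(signatures$members, intersect, universe)
  .dysreg_profile(sets, dysreg, universe, alternative)
}

#' Per-subcluster dysregulation profile
#'
#' As [signature_dysregulation_profile], with the enriched transcript set of
#' each single-cell lineage subcluster as denominator. Subcluster enriched
#' sets must already be contained in the universe; a violation signals that
#' the conservative-universe rule was broken upstream.
#'
#' @param subclusters A `subcluster_table` (see [simulate_subcluster_table])
#'   or data frame with columns `lineage`, `subcluster` and a list-column
#'   `enriched`.
#' @inheritParams signature_dysregulation_profile
#' @return Data frame with `lineage`, `subcluster` and the profile columns.
#' @export
subcluster_dysregulation_profile <- function(subclusters, dysreg, universe,
                                             alternative = "greater") {
  sets <- subclusters$enriched
  names(sets) <- paste(subclusters$lineage, subclusters$subcluster, sep = ":")
  prof <- .dysreg_profile(sets, dysreg, universe, alternative)
  cbind(subclusters[, c("lineage", "subcluster")], prof[, -1])
}

#' Assign N/TS, P and M state labels to lineage subclusters
#'
#' Within each lineage, subclusters are labeled from two observables: the
#' fraction of their enriched transcripts dysregulated by irradiation (a
#' proxy for radiosensitive, neoblast-proximal expression) and their mean
#' piwi-1 level. Neoblast/transition-state (N/TS) subclusters sit above both
#' high thresholds; mature (M) subclusters have negligible piwi-1 and the
#' lowest irradiation tier; everything else is progeny (P). A manual
#' override table takes precedence, mirroring hand-assignment of
#' well-characterized lineages.
#'
#' @param subclusters `subcluster_table` or data frame with columns
#'   `lineage`, `subcluster`, `piwi_level` and `irr_frac` (fraction in
#'   \[0, 1\] of enriched transcripts dysregulated by irradiation). If
#'   `irr_frac` is missing it can be supplied separately.
#' @param irr_frac Optional numeric vector overriding/providing the
#'   irradiation-dysregulated fraction per row.
#' @param piwi_neg_frac Piwi level below this fraction of the lineage
#'   maximum counts as negligible (default 0.05).
#' @param piwi_high_frac Piwi level at or above this fraction of the lineage
#'   maximum counts as high (default 0.5).
#' @param irr_high_quantile,irr_low_quantile Within-lineage quantiles
#'   bounding the high and low irradiation tiers (defaults 2/3 and 1/3,
#'   i.e. tertiles).
#' @param overrides Optional data frame `lineage`, `subcluster`, `state`
#'   hard-assigning labels.
#' @return The input with a `state` column in
#'   `{"N/TS", "P", "M", "unassigned"}`.
#' @export
classify_subcluster_states <- function(subclusters, irr_frac = NULL,
                                       piwi_neg_frac = 0.05,
                                       piwi_high_frac = 0.5,
                                       irr_high_quantile = 2 / 3,
                                       irr_low_quantile = 1 / 3,
                                       overrides = NULL) {
  tab <- subclusters
  if (!is.null(irr_frac)) tab$irr_frac <- irr_frac
  if (is.null(tab$irr_frac))
    stop("irradiation-dysregulated fractions required for classification")
  tab$state <- NA_character_
  for (ln in unique(tab$lineage)) {
    i <- which(tab$lineage == ln)
    irr <- tab$irr_frac[i]
    piwi <- tab$piwi_level[i]
    q_hi <- stats::quantile(irr, irr_high_quantile, names = FALSE)
    q_lo <- stats::quantile(irr, irr_low_quantile, names = FALSE)
    pmax_ <- max(piwi)
    st <- rep("P", length(i))
    st[irr >= q_hi & piwi >= piwi_high_frac * pmax_] <- "N/TS"
    st[piwi < piwi_neg_frac * pmax_ & irr <= q_lo] <- "M"
    if (!any(st == "N/TS")) {
      warning("no N/TS subcluster identified in lineage ", ln,
              "; marking lineage unassigned")
      st[] <- "unassigned"
    }
    tab$state[i] <- st
  }
  if (!is.null(overrides)) {
    key <- paste(tab$lineage, tab$subcluster)
    okey <- paste(overrides$lineage, overrides$subcluster)
    hit <- match(key, okey)
    tab$state[!is.na(hit)] <- overrides$state[hit[!is.na(hit)]]
  }
  tab
}

#' Pooled dysregulation percentages by cell-state class
#'
#' Averages per-subcluster dysregulation percentages within each state class
#' (N/TS, P, M), per lineage and pooled, and reports the ordering statistic
#' mean(P, M) - mean(N/TS): positive when progeny- and mature-state
#' transcripts are preferentially dysregulated (the differentiation-delay
#' pattern), negative when neoblast-state transcripts are (the
#' irradiation-ablation pattern).
#'
#' @param profile Data frame from [subcluster_dysregulation_profile].
#' @param states Character vector of state labels aligned with `profile`
#'   rows (or a `state` column already present in `profile`).
#' @return List with `by_lineage` (lineage x state mean percentages),
#'   `pooled` (state means over all subclusters) and `ordering_statistic`.
#' @export
lineage_profile_summary <- function(profile, states = profile$state) {
  stopifnot(length(states) == nrow(profile))
  pct <- profile$pct_up + profile$pct_down
  keep <- states %in% c("N/TS", "P", "M") & !is.na(pct)
  prof <- profile[keep, , drop = FALSE]
  st <- factor(states[keep], levels = c("N/TS", "P", "M"))
  pct <- pct[keep]
  by_lineage <- as.data.frame.matrix(
    tapply(pct, list(prof$lineage, st), mean))
  pooled <- tapply(pct, st, mean)
  ordering <- mean(pooled[c("P", "M")], na.rm = TRUE) - pooled[["N/TS"]]
  list(by_lineage = by_lineage,
       pooled = data.frame(state = names(pooled), mean_pct = as.numeric(pooled)),
       ordering_statistic = unname(ordering))
}
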