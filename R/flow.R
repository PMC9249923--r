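#' Calibrate X1/X2/Xins gates from paired untreated and irradiated samples
#'
#' Automates the standard calibration of planarian Hoechst flow gates: the
#' DNA-content threshold separating >2C (X1) from 2C events and the marker
#' threshold separating X2 from Xins within the 2C population are chosen by
#' a deterministic grid search minimizing squared deviation from the
#' calibration criteria — untreated proportions of approximately 15% (X1),
#' 25% (X2) and 60% (Xins), at least 95% X1 depletion (hinge penalty) and
#' about 70% X2 depletion in the 4-day post-irradiation sample. The DNA
#' threshold is constrained to the valley between the 2C and 4C peaks.
#'
#' PIWI gating thresholds are derived from the untreated marker
#' distribution: `theta_lo` is the X2/Xins marker threshold and `theta_hi`
#' the density valley separating the two upper marker modes on the log
#' scale. The <4C/4C sub-threshold `theta_4c` is placed at the density
#' valley below the 4C peak (fallback 3.5C).
#'
#' @param untreated,irradiated `event_table` data frames (see
#'   [simulate_flow_events]) with at least 5000 events each.
#' @param dna_grid_length,marker_grid_length Grid resolution (defaults 60).
#' @param hinge_weight Weight on the squared hinge penalty for X1 depletion
#'   below 95% (default 4).
#' @return Object of class `gate_set`: thresholds `theta_dna`,
#'   `theta_marker`, `theta_lo`, `theta_hi`, `theta_4c` and `achieved`
#'   (untreated percentages, depletions, objective and hinge penalty).
#' @export
draw_gates <- function(untreated, irradiated,
                       dna_grid_length = 60, marker_grid_length = 60,
                       hinge_weight = 4) {
  if (nrow(untreated) < 5000 || nrow(irradiated) < 5000)
    stop("calibration requires at least 5000 events per sample")
  pk <- .dna_peaks(untreated$dna)
  dna_grid <- seq(pk$mode2c + 0.05, pk$mode4c - 0.05,
                  length.out = dna_grid_length)
  marker_grid <- stats::quantile(untreated$marker,
                                 probs = seq(0.2, 0.95,
                                             length.out = marker_grid_length),
                                 names = FALSE)
  # Exact gate counts for every grid pair via a 2-D histogram with
  # cumulative sums: O(events + grid^2) instead of O(events * grid^2).
  gc_u <- .gate_counts(untreated, dna_grid, marker_grid)
  gc_i <- .gate_counts(irradiated, dna_grid, marker_grid)
  x1 <- 100 * gc_u$x1 / gc_u$n          # length(dna_grid)
  x2 <- 100 * gc_u$x2 / gc_u$n          # dna x marker matrix
  x1i <- 100 * gc_i$x1 / gc_i$n
  x2i <- 100 * gc_i$x2 / gc_i$n
  dep1 <- ifelse(x1 > 0, 100 * (x1 - x1i) / x1, 0)
  dep2 <- ifelse(x2 > 0, 100 * (x2 - x2i) / x2, 0)
  hinge <- pmax(0, 95 - dep1)
  obj <- (x1 - 15)^2 + sweep((x2 - 25)^2, 1, hinge_weight * hinge^2, "+") +
    (100 - sweep(x2, 1, x1, "+") - 60)^2 + (dep2 - 70)^2
  idx <- arrayInd(which.min(obj), dim(obj))
  i <- idx[1]; j <- idx[2]
  best <- list(theta_dna = dna_grid[i], theta_marker = marker_grid[j],
               objective = obj[i, j], x1 = x1[i], x2 = x2[i, j],
               xins = 100 - x1[i] - x2[i, j],
               x1_depletion = dep1[i], x2_depletion = dep2[i, j],
               hinge_penalty = hinge[i])
  theta_4c <- .valley_below(untreated$dna, pk$mode4c, fallback = 3.5)
  piwi <- .piwi_thresholds(untreated$marker, best$theta_marker)
  structure(list(theta_dna = best$theta_dna,
                 theta_marker = best$theta_marker,
                 theta_lo = piwi$lo, theta_hi = piwi$hi,
                 theta_4c = theta_4c,
                 achieved = best[c("x1", "x2", "xins", "x1_depletion",
                                   "x2_depletion", "objective",
                                   "hinge_penalty")]),
            class = "gate_set")
}

# Histogram-based gate counts. For threshold pair (dna_grid[i],
# marker_grid[j]): x1[i] = #events with dna > dna_grid[i];
# x2[i, j] = #events with dna <= dna_grid[i] and marker > marker_grid[j].
.gate_counts <- function(events, dna_grid, marker_grid) {
  nd <- length(dna_grid); nm <- length(marker_grid)
  di <- findInterval(events$dna, dna_grid)        # 0..nd
  mi <- findInterval(events$marker, marker_grid)  # 0..nm
  H <- matrix(tabulate(di * (nm + 1) + mi + 1, nbins = (nd + 1) * (nm + 1)),
              nrow = nd + 1, ncol = nm + 1, byrow = TRUE)
  dna_tot <- rowSums(H)
  # events with dna > dna_grid[i] have di >= i
  x1 <- rev(cumsum(rev(dna_tot)))[-1]
  # cumulative over dna (<= threshold) then suffix over marker (> threshold)
  Hc <- apply(H, 2, cumsum)                       # dna-prefix counts
  x2full <- t(apply(Hc[-(nd + 1), , drop = FALSE], 1, function(r)
    rev(cumsum(rev(r)))))
  x2 <- x2full[, -1, drop = FALSE]                # drop marker <= min bin
  list(x1 = x1, x2 = x2, n = nrow(events))
}

# Locate 2C and 4C modes of the DNA-content density; error when the
# distribution is not bimodal (calibration impossible).
.dna_peaks <- function(dna) {
  d <- stats::density(dna, n = 512)
  loc_max <- which(diff(sign(diff(d$y))) == -2) + 1
  lo <- loc_max[d$x[loc_max] >= 1.2 & d$x[loc_max] < 3]
  hi <- loc_max[d$x[loc_max] >= 3 & d$x[loc_max] <= 5]
  if (!length(lo) || !length(hi))
    stop("bimodal DNA-content structure absent: cannot calibrate gates")
  list(mode2c = d$x[lo[which.max(d$y[lo])]],
       mode4c = d$x[hi[which.max(d$y[hi])]],
       density = d)
}

# Density valley immediately below a peak position.
.valley_below <- function(v, peak, fallback) {
  d <- stats::density(v, n = 512)
  loc_min <- which(diff(sign(diff(d$y))) == 2) + 1
  cand <- loc_min[d$x[loc_min] < peak & d$x[loc_min] > 2.2]
  if (!length(cand)) return(fallback)
  d$x[cand[which.min(d$y[cand])]]
}

# PIWI-HI threshold: deepest density valley of log(marker) above the LO
# threshold that leaves at least 10% of the upper population on each side
# (so shallow tail notches are ignored); falls back to the median.
.piwi_thresholds <- function(marker, theta_lo) {
  upper <- log(marker[marker > theta_lo & marker > 0])
  hi <- if (length(upper) > 100) {
    d <- stats::density(upper, n = 512)
    loc_min <- which(diff(sign(diff(d$y))) == 2) + 1
    frac_left <- vapply(d$x[loc_min], function(x) mean(upper < x),
                        numeric(1))
    loc_min <- loc_min[frac_left >= 0.1 & frac_left <= 0.9]
    if (length(loc_min)) exp(d$x[loc_min[which.min(d$y[loc_min])]])
    else exp(stats::median(upper))
  } else exp(stats::median(upper))
  list(lo = theta_lo, hi = hi)
}

#' @export
print.gate_set <- function(x, ...) {
  cat("gate_set: theta_dna =", round(x$theta_dna, 3),
      "C, theta_marker =", signif(x$theta_marker, 4),
      ", theta_hi =", signif(x$theta_hi, 4),
      ", theta_4c =", round(x$theta_4c, 3), "C\n")
  a <- x$achieved
  cat(sprintf("calibration: X1 %.1f%% X2 %.1f%% Xins %.1f%% | X1 depletion %.1f%% X2 depletion %.1f%%\n",
              a$x1, a$x2, a$xins, a$x1_depletion, a$x2_depletion))
  invisible(x)
}

#' Write / read a gate set as JSON
#' @param gates A `gate_set`.
#' @param path File path.
#' @export
write_gates <- function(gates, path) {
  jsonlite::write_json(unclass(gates), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "gate_set")
}

#' Quantify X1/X2/Xins fraction percentages
#'
#' X1 = events with DNA content above `theta_dna`; X2 = remaining events
#' with marker above `theta_marker`; Xins = the rest. Percentages of total
#' events; they sum to 100 by construction.
#'
#' @param events An `event_table`.
#' @param gates A `gate_set`.
#' @return Named numeric vector `c(X1, X2, Xins)` in percent.
#' @export
quantify_fractions <- function(events, gates) {
  if (!nrow(events)) stop("empty event table")
  x1 <- events$dna > gates$theta_dna
  x2 <- !x1 & events$marker > gates$theta_marker
  c(X1 = 100 * mean(x1), X2 = 100 * mean(x2),
    Xins = 100 * mean(!x1 & !x2))
}

#' Quantify PIWI-HI / PIWI-LO / PIWI-NEG percentages
#'
#' HI = marker at or above `theta_hi`; LO = marker in
#' \[`theta_lo`, `theta_hi`); NEG = the rest.
#'
#' @inheritParams quantify_fractions
#' @return Named numeric vector `c("PIWI-HI", "PIWI-LO", "PIWI-NEG")` in
#'   percent.
#' @export
marker_fractions <- function(events, gates) {
  if (!nrow(events)) stop("empty event table")
  if (gates$theta_hi <= gates$theta_lo)
    stop("theta_hi must exceed theta_lo")
  hi <- events$marker >= gates$theta_hi
  lo <- !hi & events$marker >= gates$theta_lo
  c("PIWI-HI" = 100 * mean(hi), "PIWI-LO" = 100 * mean(lo),
    "PIWI-NEG" = 100 * mean(!hi & !lo))
}

#' Cell-cycle subfractions within a gate
#'
#' Splits the events of a gate (typically X1) at the 4C sub-threshold:
#' events with DNA below `theta_4c` are in G0/G1 or S phase, events at or
#' above it in G2/M.
#'
#' @param events_in_gate Events already restricted to a gate.
#' @param theta_4c Threshold in C units (e.g. `gates$theta_4c`).
#' @return Named vector `c(pct_lt4C, pct_4C)`; the two sum to 100.
#' @export
cell_cycle_subfractions <- function(events_in_gate, theta_4c) {
  if (!nrow(events_in_gate)) stop("empty gate")
  lt <- 100 * mean(events_in_gate$dna < theta_4c)
  c(pct_lt4C = lt, pct_4C = 100 - lt)
}

#' Percent change of a fraction percentage
#'
#' @param percent_before,percent_after Percentages before and after a
#'   treatment; `percent_before` must be positive.
#' @return `100 * (after - before) / before` (negative for a reduction).
#' @export
fraction_change <- function(percent_before, percent_after) {
  if (any(percent_before <= 0)) stop("baseline percentage must be positive")
  100 * (percent_after - percent_before) / percent_before
}
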