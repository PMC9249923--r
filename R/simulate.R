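#' Default cell states of the composition model
#'
#' Five states span the planarian differentiation axis: cycling neoblasts
#' (S/G2/M, the X1 gate), G1 neoblasts and post-mitotic early progeny
#' (together the X2 gate), and late progeny plus mature cells (the Xins
#' gate). PIWI-1 marker levels decrease monotonically along the lineage:
#' high in neoblasts, low (perduring protein) in early progeny, negligible
#' in mature cells.
#'
#' @return Character vector of the five state names.
#' @export
planstate_states <- function() {
  c("cycling_neoblast", "g1_neoblast", "early_progeny", "late_progeny",
    "mature")
}

.default_piwi <- c(cycling_neoblast = 150, g1_neoblast = 120,
                   early_progeny = 40, late_progeny = 12, mature = 1.5)
.default_scatter <- c(cycling_neoblast = 1, g1_neoblast = 1,
                      early_progeny = 1.2, late_progeny = 1.8, mature = 2.5)

#' Simulation configuration
#'
#' Bundles the tunable parameters of all generators. Defaults describe a
#' desk-scale whole-animal experiment: 2000 transcripts of which 100 per
#' state are enriched 8-fold, library sizes near one million, NB dispersion
#' 0.01 (variance = mean + phi * mean^2; the biological coefficient of
#' variation of 0.1 typical of genetically identical model organisms), and 50,000 flow events with a 5%
#' DNA-content coefficient of variation.
#'
#' @param n_transcripts Number of transcripts (>= 50).
#' @param n_enriched Enriched transcripts per state.
#' @param enrichment_fold Expression fold of an enriched transcript in its
#'   state relative to all other states (> 1).
#' @param replicates Bulk replicates per condition/fraction.
#' @param libsize_range Range library sizes are drawn from (uniform).
#' @param dispersion NB dispersion, scalar or per-transcript.
#' @param flow_events Events per flow sample.
#' @param dna_cv Coefficient of variation of the 2C and 4C DNA peaks.
#' @param marker_sdlog Log-normal spread of marker intensity around the
#'   state's piwi level.
#' @param scatter_sdlog Log-normal spread of the side-scatter surrogate.
#' @param s_fraction Fraction of cycling-neoblast events in S phase (the
#'   rest are G2/M).
#' @param ablation Probability that a radiosensitive event is removed by
#'   irradiation.
#' @param progeny_sensitivity Probability that an early-progeny event is
#'   radiosensitive. The default (0.72) is the 4-day post-irradiation
#'   calibration regime; [irradiation_preset] provides the 24-h value.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000, n_enriched = 100,
                       enrichment_fold = 8, replicates = 3,
                       libsize_range = c(8e5, 1.2e6), dispersion = 0.01,
                       flow_events = 50000, dna_cv = 0.05,
                       marker_sdlog = 0.35, scatter_sdlog = 0.3,
                       s_fraction = 0.6, ablation = 0.975,
                       progeny_sensitivity = 0.72) {
  stopifnot(n_transcripts >= 50, enrichment_fold > 0, all(dispersion > 0),
            replicates >= 1, dna_cv > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Irradiation presets
#'
#' The 4-day regime (the gating calibration regime) removes essentially all
#' neoblasts and about 70% of X2-resident early progeny; the 24-h regime
#' spares more progeny, depleting the X2 gate by roughly half.
#'
#' @param preset `"4dpi"` or `"24h"`.
#' @return List with `ablation` and `progeny_sensitivity`.
#' @export
irradiation_preset <- function(preset = c("4dpi", "24h")) {
  preset <- match.arg(preset)
  switch(preset,
         "4dpi" = list(ablation = 0.975, progeny_sensitivity = 0.72),
         "24h" = list(ablation = 0.975, progeny_sensitivity = 0.48))
}

#' Generate per-state expression programs
#'
#' Each state receives a disjoint block of `n_enriched` transcripts whose
#' expected expression is `enrichment_fold` times the transcript's baseline
#' in that state and baseline elsewhere; all remaining transcripts are
#' expressed at baseline in every state. Baselines are log-normal across
#' transcripts. Columns of the returned `mu` are scaled to sum to one
#' (relative expression); the unscaled matrix is kept as `mu_raw`.
#'
#' @param n_transcripts Number of transcripts (>= 50).
#' @param enrichment_fold Fold enrichment (> 1 for a real signal; 1 gives
#'   the degenerate no-enrichment case).
#' @param seed Random seed (fixed seed gives identical output).
#' @param n_enriched Enriched transcripts per state (default 5% of
#'   transcripts).
#' @param states State names (default [planstate_states]).
#' @param piwi_level Named marker level per state; must decrease from
#'   cycling neoblast through early progeny to mature.
#' @param baseline_sdlog Log-normal spread of baseline expression.
#' @return Object of class `state_programs`: list with `states`, `mu`,
#'   `mu_raw`, `enriched` (named list of transcript ids per state) and
#'   `piwi_level`.
#' @export
make_state_programs <- function(n_transcripts, enrichment_fold = 8,
                                seed = NULL,
                                n_enriched = max(5, round(0.05 * n_transcripts)),
                                states = planstate_states(),
                                piwi_level = .default_piwi[states],
                                baseline_sdlog = 0.5) {
  stopifnot(n_transcripts >= 50, enrichment_fold >= 1)
  if (length(states) * n_enriched > 0.8 * n_transcripts)
    stop("configuration error: too few transcripts for ",
         length(states), " enriched blocks of ", n_enriched)
  pw <- piwi_level
  if (all(c("cycling_neoblast", "early_progeny", "mature") %in% names(pw)) &&
      !(pw["cycling_neoblast"] > pw["early_progeny"] &&
        pw["early_progeny"] > pw["mature"]))
    stop("piwi levels must decrease from cycling neoblast to mature")
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("t%05d", seq_len(n_transcripts))
  baseline <- stats::rlnorm(n_transcripts, meanlog = 0,
                            sdlog = baseline_sdlog)
  picked <- sample(n_transcripts, length(states) * n_enriched)
  blocks <- split(picked, rep(seq_along(states), each = n_enriched))
  mu_raw <- matrix(baseline, n_transcripts, length(states),
                   dimnames = list(ids, states))
  for (s in seq_along(states))
    mu_raw[blocks[[s]], s] <- baseline[blocks[[s]]] * enrichment_fold
  enriched <- lapply(blocks, function(b) ids[b])
  names(enriched) <- states
  structure(list(states = states,
                 mu = sweep(mu_raw, 2, colSums(mu_raw), "/"),
                 mu_raw = mu_raw, enriched = enriched,
                 piwi_level = pw),
            class = "state_programs")
}

#' @export
print.state_programs <- function(x, ...) {
  cat("state_programs:", nrow(x$mu), "transcripts,",
      length(x$states), "states,",
      length(x$enriched[[1]]), "enriched per state\n")
  invisible(x)
}

#' Whole-animal cell-state composition
#'
#' Mixture weights of the five states in an unperturbed animal, chosen so
#' that calibrated flow gates capture approximately 15% (X1), 25% (X2) and
#' 60% (Xins) of events (the cycling weight slightly exceeds 0.15 to
#' compensate for S-phase events falling below the DNA threshold).
#'
#' @param w Named nonnegative weights, one per state; normalized to sum 1.
#' @return Object of class `cell_composition`: list with `w` and the state
#'   role sets used by [perturb_composition].
#' @export
cell_composition <- function(w = c(cycling_neoblast = 0.165,
                                   g1_neoblast = 0.09,
                                   early_progeny = 0.145,
                                   late_progeny = 0.05,
                                   mature = 0.55)) {
  stopifnot(all(w >= 0), sum(w) > 0, !is.null(names(w)))
  structure(list(
    w = w / sum(w),
    progeny = intersect(c("early_progeny", "late_progeny"), names(w)),
    mature_states = intersect("mature", names(w)),
    neoblast = intersect(c("cycling_neoblast", "g1_neoblast"), names(w)),
    partially_sensitive = intersect("early_progeny", names(w))),
    class = "cell_composition")
}

#' @export
print.cell_composition <- function(x, ...) {
  cat("cell_composition:\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Perturb a cell-state composition
#'
#' Differentiation delay multiplies the progeny-state weights by `delta`
#' (progeny accumulate because maturation is slowed) and optionally
#' decrements the mature weight by `mature_factor`. Irradiation multiplies
#' the radiosensitive neoblast weights by `(1 - ablation)` and the
#' partially sensitive early-progeny weight by
#' `(1 - ablation * progeny_sensitivity)`. Weights are renormalized to
#' sum 1.
#'
#' @param comp A `cell_composition`.
#' @param delta Delay factor, >= 0 (1 = no delay).
#' @param ablation Fraction of radiosensitive cells removed, in \[0, 1\].
#' @param mature_factor Multiplier on mature-state weights (default 1).
#' @param progeny_sensitivity Radiosensitive fraction of early progeny
#'   (default the 4-dpi preset, 0.72).
#' @return A perturbed, renormalized `cell_composition`.
#' @export
perturb_composition <- function(comp, delta = 1, ablation = 0,
                                mature_factor = 1,
                                progeny_sensitivity = 0.72) {
  stopifnot(inherits(comp, "cell_composition"), delta >= 0,
            ablation >= 0, ablation <= 1)
  w <- comp$w
  w[comp$progeny] <- w[comp$progeny] * delta
  w[comp$mature_states] <- w[comp$mature_states] * mature_factor
  w[comp$neoblast] <- w[comp$neoblast] * (1 - ablation)
  w[comp$partially_sensitive] <-
    w[comp$partially_sensitive] * (1 - ablation * progeny_sensitivity)
  if (sum(w) <= 0) stop("degenerate composition: all weights zero")
  out <- comp
  out$w <- w / sum(w)
  out
}

#' Simulate whole-animal bulk RNA-seq counts
#'
#' Per-transcript expected expression is the composition-weighted mixture of
#' the state programs; counts are negative binomial with
#' variance = mean + phi * mean^2 around `libsize * mixture mean`.
#'
#' @param programs A `state_programs`.
#' @param composition A `cell_composition`.
#' @param config A `sim_config` (supplies replicates, library-size range
#'   and dispersion).
#' @param group Group label for the samples.
#' @param n_reps Number of replicates (default `config$replicates`).
#' @param seed Random seed.
#' @return A `count_matrix`.
#' @export
simulate_bulk_counts <- function(programs, composition,
                                 config = sim_config(), group = "control",
                                 n_reps = config$replicates, seed = NULL) {
  stopifnot(inherits(programs, "state_programs"),
            inherits(composition, "cell_composition"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- composition$w[programs$states]
  mean_rel <- as.vector(programs$mu %*% (w / sum(w)))
  G <- nrow(programs$mu)
  phi <- rep_len(config$dispersion, G)
  lib <- round(stats::runif(n_reps, config$libsize_range[1],
                            config$libsize_range[2]))
  counts <- vapply(seq_len(n_reps), function(j)
    stats::rnbinom(G, size = 1 / phi, mu = lib[j] * mean_rel),
    numeric(G))
  rownames(counts) <- rownames(programs$mu)
  colnames(counts) <- paste0(group, "_", seq_len(n_reps))
  count_matrix(counts, rep(group, n_reps))
}

# Fraction-specific compositions: each sorted fraction is concentrated on
# the states it captures, with equal weights within the fraction.
.fraction_compositions <- function(scheme = c("X", "PIWI")) {
  scheme <- match.arg(scheme)
  if (scheme == "X")
    list(X1 = c(cycling_neoblast = 1),
         X2 = c(g1_neoblast = 0.5, early_progeny = 0.5),
         Xins = c(late_progeny = 0.5, mature = 0.5))
  else
    list("PIWI-HI" = c(cycling_neoblast = 0.5, g1_neoblast = 0.5),
         "PIWI-LO" = c(early_progeny = 1),
         "PIWI-NEG" = c(late_progeny = 0.5, mature = 0.5))
}

#' Which fraction should recover each state's enriched transcripts
#'
#' @param scheme `"X"` or `"PIWI"`.
#' @return Named character vector mapping state to fraction.
#' @export
state_fraction_map <- function(scheme = c("X", "PIWI")) {
  scheme <- match.arg(scheme)
  if (scheme == "X")
    c(cycling_neoblast = "X1", g1_neoblast = "X2", early_progeny = "X2",
      late_progeny = "Xins", mature = "Xins")
  else
    c(cycling_neoblast = "PIWI-HI", g1_neoblast = "PIWI-HI",
      early_progeny = "PIWI-LO", late_progeny = "PIWI-NEG",
      mature = "PIWI-NEG")
}

#' Simulate sorted-fraction bulk counts
#'
#' One group per fraction (X1/X2/Xins or PIWI-HI/LO/NEG), each simulated as
#' bulk RNA-seq of a composition concentrated on the states that fraction
#' captures.
#'
#' @inheritParams simulate_bulk_counts
#' @param scheme `"X"` (default) or `"PIWI"`.
#' @return A `count_matrix` with one group per fraction.
#' @export
simulate_fraction_counts <- function(programs, config = sim_config(),
                                     scheme = c("X", "PIWI"), seed = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  comps <- .fraction_compositions(scheme)
  mats <- lapply(names(comps), function(f) {
    w <- numeric(length(programs$states))
    names(w) <- programs$states
    w[names(comps[[f]])] <- comps[[f]]
    simulate_bulk_counts(programs, cell_composition(w), config, group = f)
  })
  do.call(cbind_counts, mats)
}

#' Simulate a single-cell lineage subcluster table
#'
#' Emulates published per-lineage subcluster enrichment tables: each lineage
#' contributes one subcluster per cell state, carrying an enriched
#' transcript list drawn mostly from that state's enriched block (plus a
#' configurable fraction of background transcripts), a noisy mean piwi-1
#' level, a noisy irradiation-dysregulated fraction, and the latent true
#' state label (`N/TS` for neoblast states, `P` for progeny, `M` for
#' mature) retained for testing.
#'
#' @param programs A `state_programs`.
#' @param lineages Character vector of lineage names (may be empty).
#' @param irradiation_sensitivity Named per-state expected fraction of
#'   enriched transcripts dysregulated by irradiation.
#' @param seed Random seed.
#' @param n_per_subcluster Enriched transcripts listed per subcluster.
#' @param background_frac Fraction of each list drawn from non-enriched
#'   transcripts.
#' @param piwi_noise_sdlog Log-normal noise on the piwi level.
#' @param irr_noise_sd Gaussian noise on the irradiation fraction.
#' @return A `subcluster_table` data frame with columns `lineage`,
#'   `subcluster`, `state_true`, `piwi_level`, `irr_frac` and list-column
#'   `enriched`.
#' @export
simulate_subcluster_table <- function(programs, lineages,
                                      irradiation_sensitivity =
                                        c(cycling_neoblast = 0.9,
                                          g1_neoblast = 0.85,
                                          early_progeny = 0.45,
                                          late_progeny = 0.15,
                                          mature = 0.05),
                                      seed = NULL, n_per_subcluster = 30,
                                      background_frac = 0.2,
                                      piwi_noise_sdlog = 0.25,
                                      irr_noise_sd = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  empty <- data.frame(lineage = character(), subcluster = character(),
                      state_true = character(), piwi_level = numeric(),
                      irr_frac = numeric())
  empty$enriched <- list()
  class(empty) <- c("subcluster_table", "data.frame")
  if (!length(lineages)) return(empty)
  truth <- c(cycling_neoblast = "N/TS", g1_neoblast = "N/TS",
             early_progeny = "P", late_progeny = "P", mature = "M")
  all_ids <- rownames(programs$mu)
  bg_pool <- setdiff(all_ids, unlist(programs$enriched))
  n_bg <- round(background_frac * n_per_subcluster)
  n_core <- n_per_subcluster - n_bg
  rows <- list()
  for (ln in lineages) {
    for (s in programs$states) {
      block <- programs$enriched[[s]]
      core <- sample(block, min(n_core, length(block)))
      bg <- if (n_bg > 0) sample(bg_pool, n_bg) else character()
      rows[[length(rows) + 1]] <- list(
        lineage = ln,
        subcluster = paste0(ln, "_", s),
        state_true = unname(truth[s]),
        piwi_level = programs$piwi_level[[s]] *
          stats::rlnorm(1, 0, piwi_noise_sdlog),
        irr_frac = min(1, max(0, stats::rnorm(
          1, irradiation_sensitivity[[s]], irr_noise_sd))),
        enriched = list(c(core, bg)))
    }
  }
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(lineage = r$lineage, subcluster = r$subcluster,
               state_true = r$state_true, piwi_level = r$piwi_level,
               irr_frac = r$irr_frac)))
  tab$enriched <- lapply(rows, function(r) r$enriched[[1]])
  class(tab) <- c("subcluster_table", "data.frame")
  tab
}

#' Write / read a subcluster table as TSV
#'
#' The enriched transcript list is serialized comma-separated.
#'
#' @param tab A `subcluster_table`.
#' @param path File path.
#' @export
write_subclusters <- function(tab, path) {
  df <- as.data.frame(tab[, setdiff(names(tab), "enriched")])
  df$enriched <- vapply(tab$enriched, paste, character(1), collapse = ",")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subclusters
#' @export
read_subclusters <- function(path) {
  df <- utils::read.delim(path)
  df$enriched <- strsplit(df$enriched, ",", fixed = TRUE)
  class(df) <- c("subcluster_table", "data.frame")
  df
}

#' Simulate a sparse single-cell detection matrix
#'
#' Per-cell Poisson counts at depth `depth` over the state programs, as a
#' sparse transcripts-by-cells matrix; used to exercise the 0.5%-of-cells
#' detection rule. The cell-to-subcluster assignment is returned as an
#' attribute `cells` (here one subcluster per state).
#'
#' @param programs A `state_programs`.
#' @param cells_per_state Cells simulated per state.
#' @param depth Expected counts per cell.
#' @param seed Random seed.
#' @return A `dgCMatrix` with a `cells` attribute (character vector of
#'   state/subcluster labels per column).
#' @export
simulate_sc_detection <- function(programs, cells_per_state = 200,
                                  depth = 500, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- nrow(programs$mu)
  states <- programs$states
  cols <- list()
  labels <- character()
  for (s in states) {
    lam <- depth * programs$mu[, s]
    cnt <- matrix(stats::rpois(G * cells_per_state, lam), G,
                  cells_per_state)
    cols[[s]] <- cnt
    labels <- c(labels, rep(s, cells_per_state))
  }
  m <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
  rownames(m) <- rownames(programs$mu)
  colnames(m) <- paste0("cell", seq_len(ncol(m)))
  attr(m, "cells") <- labels
  m
}

#' Write a sparse matrix as MatrixMarket triplets
#'
#' Writes `<stem>.mtx` plus `<stem>.rows.txt` and `<stem>.cols.txt`.
#'
#' @param m A sparse matrix with dimnames.
#' @param stem Path stem.
#' @export
write_mtx <- function(m, stem) {
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(stem, ".mtx"))
  writeLines(rownames(m), paste0(stem, ".rows.txt"))
  writeLines(colnames(m), paste0(stem, ".cols.txt"))
  invisible(stem)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(stem) {
  m <- Matrix::readMM(paste0(stem, ".mtx"))
  rownames(m) <- readLines(paste0(stem, ".rows.txt"))
  colnames(m) <- readLines(paste0(stem, ".cols.txt"))
  m
}

#' Simulate event-level flow cytometry data
#'
#' Each event draws a latent state from the composition. DNA content is a
#' 2C Gaussian peak for G0/G1 states; cycling neoblasts are uniform (2C, 4C)
#' in S phase and a 4C Gaussian in G2/M. Marker intensity is log-normal
#' around the state's piwi level, the side-scatter surrogate log-normal with
#' larger location for later states. Neoblast-state events are
#' radiosensitive; early progeny with probability
#' `config$progeny_sensitivity`. When `irradiated`, radiosensitive events
#' are removed with probability `config$ablation`.
#'
#' @param composition A `cell_composition`.
#' @param config A `sim_config`.
#' @param irradiated Apply the ablation to radiosensitive events?
#' @param seed Random seed.
#' @param piwi_level,scatter_level Named per-state location parameters.
#' @return An `event_table` data frame: `dna`, `marker`, `scatter`,
#'   `state`, `radiosensitive`.
#' @export
simulate_flow_events <- function(composition, config = sim_config(),
                                 irradiated = FALSE, seed = NULL,
                                 piwi_level = .default_piwi,
                                 scatter_level = .default_scatter) {
  stopifnot(inherits(composition, "cell_composition"),
            config$flow_events >= 1000)
  if (!is.null(seed)) set.seed(seed)
  n <- config$flow_events
  w <- composition$w
  state <- sample(names(w), n, replace = TRUE, prob = w)
  dna <- stats::rnorm(n, 2, 2 * config$dna_cv)
  cyc <- state == "cycling_neoblast"
  ncyc <- sum(cyc)
  if (ncyc) {
    in_s <- stats::runif(ncyc) < config$s_fraction
    dna_cyc <- numeric(ncyc)
    dna_cyc[in_s] <- stats::runif(sum(in_s), 2, 4)
    dna_cyc[!in_s] <- stats::rnorm(sum(!in_s), 4, 4 * config$dna_cv)
    dna[cyc] <- dna_cyc
  }
  dna <- pmax(dna, 0.5)
  marker <- stats::rlnorm(n, log(piwi_level[state]), config$marker_sdlog)
  scatter <- stats::rlnorm(n, log(scatter_level[state]),
                           config$scatter_sdlog)
  sensitive <- state %in% c("cycling_neoblast", "g1_neoblast")
  early <- state == "early_progeny"
  sensitive[early] <- stats::runif(sum(early)) < config$progeny_sensitivity
  ev <- data.frame(dna = dna, marker = marker, scatter = scatter,
                   state = state, radiosensitive = sensitive)
  if (irradiated) {
    removed <- sensitive & stats::runif(n) < config$ablation
    ev <- ev[!removed, , drop = FALSE]
    rownames(ev) <- NULL
  }
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Write / read flow events as CSV
#' @param events An `event_table`.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Simulate a qPCR Ct table
#'
#' Reference genes cycle at their nominal Ct plus noise in every sample;
#' the target gene cycles at the mean reference Ct minus log2 of the
#' condition's true fold change (so fold 1 equals the reference mean and
#' each doubling lowers Ct by one cycle), plus noise.
#'
#' @param true_fold_changes Named numeric vector: true expression fold of
#'   the target per non-calibrator condition (all > 0).
#' @param ref_cts Named numeric vector of nominal reference-gene Cts.
#' @param noise_sd Gaussian Ct noise (cycles).
#' @param seed Random seed.
#' @param target Target gene name.
#' @param calibrator Calibrator condition label.
#' @param n_replicates Samples per condition.
#' @return A data frame `sample`, `condition`, `gene`, `ct`.
#' @export
simulate_ct_table <- function(true_fold_changes, ref_cts, noise_sd = 0.15,
                              seed = NULL, target = "target",
                              calibrator = "control", n_replicates = 3) {
  stopifnot(all(true_fold_changes > 0), length(ref_cts) >= 1,
            !is.null(names(ref_cts)))
  if (!is.null(seed)) set.seed(seed)
  folds <- c(stats::setNames(1, calibrator), true_fold_changes)
  rows <- list()
  for (cond in names(folds)) {
    for (r in seq_len(n_replicates)) {
      smp <- paste0(cond, "_", r)
      for (g in names(ref_cts))
        rows[[length(rows) + 1]] <- data.frame(
          sample = smp, condition = cond, gene = g,
          ct = ref_cts[[g]] + stats::rnorm(1, 0, noise_sd))
      rows[[length(rows) + 1]] <- data.frame(
        sample = smp, condition = cond, gene = target,
        ct = mean(ref_cts) - log2(folds[[cond]]) +
          stats::rnorm(1, 0, noise_sd))
    }
  }
  do.call(rbind, rows)
}
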