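#' Pipeline configuration
#'
#' Validated bundle of every threshold and simulation setting consumed by
#' [run_pipeline]. The perturbed condition defaults to a differentiation
#' delay (progeny weights multiplied by 1.75, mature weight reduced by 10%); setting
#' `ablation > 0` (with `delta = 1`) turns it into an irradiation-ablation
#' condition instead.
#'
#' @param n_transcripts,n_enriched,enrichment_fold,dispersion,libsize_range
#'   Passed to the generators (see [sim_config]).
#' @param replicates_fraction Bulk replicates per sorted fraction.
#' @param replicates_condition Bulk replicates per whole-animal condition.
#' @param delta,mature_factor,ablation,progeny_sensitivity Perturbation of
#'   the test condition (see [perturb_composition]).
#' @param min_cpm,fdr_cut Expression-filter and significance thresholds.
#' @param sc_min_cell_frac Single-cell detection threshold.
#' @param prior_df Tagwise-dispersion shrinkage (prior degrees of freedom).
#' @param lineages Lineage names for the subcluster table.
#' @param flow_events Events per flow sample.
#' @param classifier Thresholds for [classify_subcluster_states].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_transcripts = 2000, n_enriched = 100,
                            enrichment_fold = 8, dispersion = 0.01,
                            libsize_range = c(8e5, 1.2e6),
                            replicates_fraction = 3,
                            replicates_condition = 4,
                            delta = 1.75, mature_factor = 0.9, ablation = 0,
                            progeny_sensitivity = 0.72,
                            min_cpm = 1, fdr_cut = 0.05,
                            sc_min_cell_frac = 0.005, prior_df = 10,
                            lineages = c("epidermis", "intestine",
                                         "protonephridia", "muscle"),
                            flow_events = 50000,
                            classifier = list(piwi_neg_frac = 0.05,
                                              piwi_high_frac = 0.5)) {
  stopifnot(n_transcripts >= 50, replicates_fraction >= 2,
            replicates_condition >= 2, delta >= 0,
            ablation >= 0, ablation <= 1, fdr_cut > 0, fdr_cut < 1,
            length(lineages) >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config]; unknown keys are an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

# Filter -> TMM -> dispersions -> all pairwise exact tests for one dataset.
.de_stage <- function(counts, min_cpm, prior_df, contrasts = NULL) {
  filt <- filter_low_expression(counts, min_cpm)
  norm <- tmm_factors(filt)
  phi <- estimate_tagwise_dispersion(filt, norm, prior_df = prior_df)
  groups <- unique(filt$samples$group)
  if (is.null(contrasts))
    contrasts <- utils::combn(groups, 2, simplify = FALSE)
  des <- lapply(contrasts, function(ct)
    nb_exact_test(filt, phi, norm, contrast = ct))
  list(filtered = filt, norm = norm, dispersion = phi, de = des)
}

#' Run the full synthetic cell-state mapping pipeline
#'
#' Executes all stages in dependency order: simulate state programs and all
#' inputs; filter/normalize/test the sorted-fraction data and derive X and
#' PIWI signatures; test the perturbed condition and the 24-h irradiation
#' reference against control; build the conservative detection universe;
#' map dysregulated transcripts onto signatures and lineage subclusters;
#' classify subcluster states from irradiation response and piwi level;
#' calibrate flow gates and quantify fractions. All stage outputs are
#' written as plain TSV/JSON files under `outdir` (when given) so any stage
#' can be re-run or swapped against real data, and a `summary.json` records
#' the headline quantities. Two runs with the same config and seed produce
#' byte-identical summaries.
#'
#' Classification uses the *downregulated* fraction of each subcluster's
#' enriched transcripts after irradiation: radiosensitivity manifests as
#' transcript loss, whereas the compensating upregulation of mature-state
#' transcripts is a renormalization artifact of RNA proportions (see the
#' package vignette).
#'
#' @param config A `pipeline_config`.
#' @param seed Integer seed controlling every stage.
#' @param outdir Output directory (created if needed); `NULL` skips file
#'   output.
#' @return Invisibly, a list with all stage objects and `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  scfg <- sim_config(n_transcripts = config$n_transcripts,
                     n_enriched = config$n_enriched,
                     enrichment_fold = config$enrichment_fold,
                     replicates = config$replicates_fraction,
                     libsize_range = config$libsize_range,
                     dispersion = config$dispersion,
                     flow_events = config$flow_events)

  programs <- make_state_programs(
    config$n_transcripts, config$enrichment_fold, seed = seed,
    n_enriched = config$n_enriched)
  control <- cell_composition()
  perturbed <- perturb_composition(control, delta = config$delta,
                                   mature_factor = config$mature_factor,
                                   ablation = config$ablation,
                                   progeny_sensitivity =
                                     config$progeny_sensitivity)
  irr24 <- irradiation_preset("24h")
  irradiated <- perturb_composition(control, ablation = irr24$ablation,
                                    progeny_sensitivity =
                                      irr24$progeny_sensitivity)

  # sorted-fraction data -> signatures (both schemes)
  frac_x <- simulate_fraction_counts(programs, scfg, "X", seed = seed + 1)
  frac_piwi <- simulate_fraction_counts(programs, scfg, "PIWI",
                                        seed = seed + 2)
  st_x <- .de_stage(frac_x, config$min_cpm, config$prior_df)
  st_piwi <- .de_stage(frac_piwi, config$min_cpm, config$prior_df)
  sig_x <- derive_fraction_signatures(st_x$de[[1]], st_x$de[[2]],
                                      st_x$de[[3]], config$fdr_cut)
  sig_piwi <- derive_fraction_signatures(st_piwi$de[[1]], st_piwi$de[[2]],
                                         st_piwi$de[[3]], config$fdr_cut)

  # whole-animal contrasts: perturbed condition and irradiation reference
  cond_counts <- cbind_counts(
    simulate_bulk_counts(programs, control, scfg, "control",
                         config$replicates_condition, seed = seed + 3),
    simulate_bulk_counts(programs, perturbed, scfg, "perturbed",
                         config$replicates_condition, seed = seed + 4))
  st_cond <- .de_stage(cond_counts, config$min_cpm, config$prior_df,
                       contrasts = list(c("perturbed", "control")))
  dys_cond <- dysregulated_sets(st_cond$de[[1]], config$fdr_cut,
                                "perturbed")

  irr_counts <- cbind_counts(
    simulate_bulk_counts(programs, control, scfg, "control",
                         config$replicates_condition, seed = seed + 5),
    simulate_bulk_counts(programs, irradiated, scfg, "irradiated",
                         config$replicates_condition, seed = seed + 6))
  st_irr <- .de_stage(irr_counts, config$min_cpm, config$prior_df,
                      contrasts = list(c("irradiated", "control")))
  dys_irr <- dysregulated_sets(st_irr$de[[1]], config$fdr_cut,
                               "irradiation-24h")

  universe <- detected_universe(st_x$filtered, st_piwi$filtered,
                                st_cond$filtered, st_irr$filtered)

  prof_x <- signature_dysregulation_profile(sig_x, dys_cond, universe)
  prof_piwi <- signature_dysregulation_profile(sig_piwi, dys_cond, universe)

  subclusters <- simulate_subcluster_table(programs, config$lineages,
                                           seed = seed + 7)
  subclusters$enriched <- lapply(subclusters$enriched, intersect,
                                 universe$members)
  irr_profile <- subcluster_dysregulation_profile(subclusters, dys_irr,
                                                  universe)
  irr_down_frac <- ifelse(irr_profile$n_set > 0,
                          irr_profile$n_down / irr_profile$n_set, 0)
  subclusters <- classify_subcluster_states(
    subclusters, irr_frac = irr_down_frac,
    piwi_neg_frac = config$classifier$piwi_neg_frac,
    piwi_high_frac = config$classifier$piwi_high_frac)
  cond_profile <- subcluster_dysregulation_profile(subclusters, dys_cond,
                                                   universe)
  cond_profile$state <- subclusters$state
  lineage_summary <- lineage_profile_summary(cond_profile)

  # flow cytometry: calibrate on an untreated/4-dpi pair, then quantify
  flow_wt <- simulate_flow_events(control, scfg, seed = seed + 8)
  flow_irr <- simulate_flow_events(control, scfg, irradiated = TRUE,
                                   seed = seed + 9)
  gates <- draw_gates(flow_wt, flow_irr)
  flow_cond <- simulate_flow_events(perturbed, scfg, seed = seed + 10)
  fractions <- rbind(
    control = quantify_fractions(flow_wt, gates),
    perturbed = quantify_fractions(flow_cond, gates),
    irradiated = quantify_fractions(flow_irr, gates))
  piwi_fracs <- rbind(
    control = marker_fractions(flow_wt, gates),
    perturbed = marker_fractions(flow_cond, gates))

  summary <- list(
    seed = seed,
    signature_sizes = c(lengths(sig_x$members), lengths(sig_piwi$members)),
    n_dysregulated = c(up = length(dys_cond$up),
                       down = length(dys_cond$down)),
    universe_size = length(universe$members),
    pct_dysregulated_x = stats::setNames(
      prof_x$pct_up + prof_x$pct_down, prof_x$set),
    pct_dysregulated_piwi = stats::setNames(
      prof_piwi$pct_up + prof_piwi$pct_down, prof_piwi$set),
    state_means = stats::setNames(lineage_summary$pooled$mean_pct,
                                  lineage_summary$pooled$state),
    ordering_statistic = lineage_summary$ordering_statistic,
    fractions = fractions,
    piwi_fractions = piwi_fracs,
    x2_change_pct = fraction_change(fractions["control", "X2"],
                                    fractions["perturbed", "X2"]))

  if (!is.null(outdir)) {
    p <- function(...) file.path(outdir, ...)
    write_counts(frac_x, p("fraction_x"))
    write_counts(frac_piwi, p("fraction_piwi"))
    write_counts(cond_counts, p("condition"))
    write_counts(irr_counts, p("irradiation"))
    for (i in seq_along(st_x$de))
      write_de_table(st_x$de[[i]], p(sprintf("de_x_%d.tsv", i)))
    write_de_table(st_cond$de[[1]], p("de_condition.tsv"))
    write_de_table(st_irr$de[[1]], p("de_irradiation.tsv"))
    write_sets(sig_x, p("signatures_x.tsv"))
    write_sets(sig_piwi, p("signatures_piwi.tsv"))
    write_sets(dys_cond, p("dysregulated_condition.tsv"))
    write_sets(dys_irr, p("dysregulated_irradiation.tsv"))
    write_sets(universe, p("universe.tsv"))
    utils::write.table(prof_x, p("profile_signatures_x.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(prof_piwi, p("profile_signatures_piwi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cond_profile, p("profile_subclusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_subclusters(subclusters, p("subclusters.tsv"))
    write_gates(gates, p("gates.json"))
    utils::write.table(data.frame(sample = rownames(fractions), fractions),
                       p("fractions.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(list(programs = programs, config = config,
                 signatures = list(X = sig_x, PIWI = sig_piwi),
                 de = list(fraction_x = st_x, fraction_piwi = st_piwi,
                           condition = st_cond, irradiation = st_irr),
                 dysregulated = list(condition = dys_cond,
                                     irradiation = dys_irr),
                 universe = universe, subclusters = subclusters,
                 profiles = list(signatures_x = prof_x,
                                 signatures_piwi = prof_piwi,
                                 subclusters = cond_profile),
                 lineage_summary = lineage_summary,
                 gates = gates, fractions = fractions,
                 summary = summary))
}
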