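test_that("state programs plant disjoint enriched blocks at the stated fold", {
  pr <- make_state_programs(1000, enrichment_fold = 8, seed = 1)
  # determinism: identical object on re-run
  expect_identical(pr, make_state_programs(1000, enrichment_fold = 8,
                                           seed = 1))
  # enriched blocks are disjoint
  all_enriched <- unlist(pr$enriched)
  expect_equal(anyDuplicated(all_enriched), 0)
  # unscaled ratio is exactly the fold for every enriched transcript
  for (s in pr$states) {
    g <- pr$enriched[[s]][1]
    others <- setdiff(pr$states, s)
    expect_equal(unname(pr$mu_raw[g, s] / pr$mu_raw[g, others]),
                 rep(8, length(others)))
  }
  # fold 1 degenerates to identical expression columns
  pr1 <- make_state_programs(200, enrichment_fold = 1, seed = 2)
  expect_equal(pr1$mu[, 1], pr1$mu[, 2], ignore_attr = TRUE)
  # too many enriched transcripts for the namespace is a config error
  expect_error(make_state_programs(60, 8, seed = 1, n_enriched = 30),
               "configuration error")
  expect_error(make_state_programs(
    200, 8, seed = 1,
    piwi_level = c(cycling_neoblast = 1, g1_neoblast = 1,
                   early_progeny = 5, late_progeny = 1, mature = 9)),
    "piwi levels")
})

test_that("composition perturbation follows the stated arithmetic", {
  w <- c(cycling_neoblast = 0.3, g1_neoblast = 0.3, early_progeny = 0.1,
         late_progeny = 0.1, mature = 0.2)
  comp <- cell_composition(w)
  # identity
  expect_equal(perturb_composition(comp, delta = 1, ablation = 0)$w,
               comp$w)
  # delta = 2 on total progeny weight 0.2: each progeny weight doubles
  # and renormalizes by 1.2
  p <- perturb_composition(comp, delta = 2)
  expect_equal(unname(p$w["early_progeny"]), 0.2 / 1.2)
  expect_equal(unname(p$w["late_progeny"]), 0.2 / 1.2)
  # full ablation removes radiosensitive states and renormalizes
  a <- perturb_composition(comp, ablation = 1, progeny_sensitivity = 1)
  expect_equal(unname(a$w["cycling_neoblast"]), 0)
  expect_equal(unname(a$w["early_progeny"]), 0)
  expect_equal(sum(a$w), 1)
  # weights always renormalize to 1
  set.seed(3)
  for (i in 1:25) {
    p <- perturb_composition(comp, delta = runif(1, 0, 4),
                             ablation = runif(1),
                             mature_factor = runif(1))
    expect_lt(abs(sum(p$w) - 1), 1e-12)
  }
  # degenerate composition errors
  only_neo <- cell_composition(c(cycling_neoblast = 1, g1_neoblast = 0,
                                 early_progeny = 0, late_progeny = 0,
                                 mature = 0))
  expect_error(perturb_composition(only_neo, ablation = 1), "degenerate")
})

test_that("bulk counts match the NB composition model", {
  pr <- make_state_programs(300, 8, seed = 4, n_enriched = 15)
  comp <- cell_composition()
  cfg <- sim_config(n_transcripts = 300, libsize_range = c(1e5, 1e5),
                    dispersion = 0.05)
  x <- simulate_bulk_counts(pr, comp, cfg, n_reps = 3, seed = 5)
  expect_identical(x$counts,
                   simulate_bulk_counts(pr, comp, cfg, n_reps = 3,
                                        seed = 5)$counts)
  # Monte-Carlo oracle: the mean over 200 replicates of each transcript
  # is within 3 SE of libsize x mixture mean
  y <- simulate_bulk_counts(pr, comp, cfg, n_reps = 200, seed = 6)
  mu <- 1e5 * as.vector(pr$mu %*% comp$w)
  se <- sqrt((mu + 0.05 * mu^2) / 200)
  g <- which.max(mu)  # check the strongest transcript plus a typical one
  for (i in c(g, 17))
    expect_lt(abs(mean(y$counts[i, ]) - mu[i]), 3 * se[i] + 1e-9)
  # Poisson limit: variance/mean ratio near 1 at tiny dispersion
  cfg0 <- sim_config(n_transcripts = 300, libsize_range = c(1e5, 1e5),
                     dispersion = 1e-8)
  z <- simulate_bulk_counts(pr, comp, cfg0, n_reps = 100, seed = 7)
  ratio <- apply(z$counts, 1, var) / rowMeans(z$counts)
  expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("fraction counts concentrate enrichment in the right group", {
  pr <- make_state_programs(300, 8, seed = 8, n_enriched = 15)
  cfg <- sim_config(n_transcripts = 300)
  x <- simulate_fraction_counts(pr, cfg, "X", seed = 9)
  expect_identical(x$counts,
                   simulate_fraction_counts(pr, cfg, "X", seed = 9)$counts)
  cp <- cpm(x)
  g <- pr$enriched$cycling_neoblast
  mean_by <- function(f) rowMeans(cp[g, x$samples$group == f, drop = FALSE])
  expect_true(all(mean_by("X1") > mean_by("X2")))
  expect_true(all(mean_by("X1") > mean_by("Xins")))
})

test_that("subcluster tables carry recoverable planted labels", {
  pr <- make_state_programs(1000, 8, seed = 10)
  tab <- simulate_subcluster_table(pr, c("epidermis", "intestine",
                                         "muscle", "gut", "neural"),
                                   seed = 11)
  expect_identical(tab$piwi_level,
                   simulate_subcluster_table(pr, c("epidermis", "intestine",
                                                   "muscle", "gut",
                                                   "neural"),
                                             seed = 11)$piwi_level)
  expect_equal(nrow(tab), 25)
  out <- classify_subcluster_states(tab)
  expect_gte(mean(out$state == out$state_true), 0.9)
  # empty lineage list gives an empty table
  expect_equal(nrow(simulate_subcluster_table(pr, character(), seed = 1)),
               0)
})

test_that("flow events reflect the composition and irradiation semantics", {
  comp <- cell_composition()
  cfg <- sim_config(flow_events = 50000)
  ev <- simulate_flow_events(comp, cfg, seed = 12)
  # state proportions within 4 binomial SE of the weights
  tab <- table(ev$state)[names(comp$w)] / nrow(ev)
  se <- sqrt(comp$w * (1 - comp$w) / nrow(ev))
  expect_true(all(abs(tab - comp$w) < 4 * se))
  # ablation = 0 leaves the irradiated table identical to untreated
  cfg0 <- sim_config(flow_events = 5000, ablation = 0)
  expect_identical(simulate_flow_events(comp, cfg0, seed = 13),
                   simulate_flow_events(comp, cfg0, irradiated = TRUE,
                                        seed = 13))
  # an all-G0/G1 composition has no events beyond the 2C noise tail
  g0 <- cell_composition(c(cycling_neoblast = 0, g1_neoblast = 0.5,
                           early_progeny = 0, late_progeny = 0,
                           mature = 0.5))
  ev0 <- simulate_flow_events(g0, cfg, seed = 14)
  expect_lt(mean(ev0$dna > 3), 1e-4)
})

test_that("synthetic Ct tables encode folds in cycle shifts", {
  refs <- c(ef2 = 18, gapdh = 16)
  ct <- simulate_ct_table(c(kd = 1), refs, noise_sd = 0, seed = 15)
  expect_equal(ct$ct[ct$gene == "target"], rep(mean(refs), 6))
  ct2 <- simulate_ct_table(c(kd = 2), refs, noise_sd = 0, seed = 15)
  expect_equal(unique(ct2$ct[ct2$gene == "target" & ct2$condition == "kd"]),
               mean(refs) - 1)
})

test_that("event tables and sparse detection matrices round-trip", {
  comp <- cell_composition()
  ev <- simulate_flow_events(comp, sim_config(flow_events = 1000),
                             seed = 16)
  path <- file.path(tempdir(), "events.csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$dna, ev$dna, tolerance = 1e-6)
  expect_equal(back$state, ev$state)

  pr <- make_state_programs(100, 8, seed = 17, n_enriched = 5)
  m <- simulate_sc_detection(pr, cells_per_state = 20, seed = 18)
  stem <- file.path(tempdir(), "scdet")
  write_mtx(m, stem)
  m2 <- read_mtx(stem)
  expect_equal(as.matrix(m2), as.matrix(m), ignore_attr = TRUE)
})
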