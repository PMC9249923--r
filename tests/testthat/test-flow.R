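# fixed gate set for unit tests that do not need calibration
fixed_gates <- structure(list(theta_dna = 2.3, theta_marker = 10,
                              theta_lo = 10, theta_hi = 70,
                              theta_4c = 3.5), class = "gate_set")

test_that("fraction quantification partitions events exactly", {
  ev <- data.frame(dna = c(rep(4, 5), rep(2, 15)),
                   marker = c(rep(100, 5), rep(100, 6), rep(1, 9)))
  f <- quantify_fractions(ev, fixed_gates)
  expect_equal(f, c(X1 = 25, X2 = 30, Xins = 45))
  expect_equal(sum(f), 100)
  # all 4C events -> X1 = 100%
  f2 <- quantify_fractions(data.frame(dna = rep(4, 10), marker = 0),
                           fixed_gates)
  expect_equal(unname(f2["X1"]), 100)
  expect_error(quantify_fractions(ev[0, ], fixed_gates), "empty")
})

test_that("marker fractions split HI/LO/NEG and validate thresholds", {
  ev <- data.frame(dna = 2, marker = c(rep(0, 6), rep(30, 3), rep(90, 1)))
  m <- marker_fractions(ev, fixed_gates)
  expect_equal(m, c("PIWI-HI" = 10, "PIWI-LO" = 30, "PIWI-NEG" = 60))
  expect_equal(sum(m), 100)
  mz <- marker_fractions(data.frame(dna = 2, marker = rep(0, 5)),
                         fixed_gates)
  expect_equal(unname(mz["PIWI-NEG"]), 100)
  bad <- fixed_gates; bad$theta_hi <- 5
  expect_error(marker_fractions(ev, bad), "theta_hi")
})

test_that("planted marker mixture is recovered within sampling error", {
  set.seed(20)
  n <- 50000
  cls <- sample(c("hi", "lo", "neg"), n, replace = TRUE,
                prob = c(0.10, 0.15, 0.75))
  marker <- c(hi = 130, lo = 35, neg = 1)[cls] *
    rlnorm(n, 0, 0.3)
  m <- marker_fractions(data.frame(dna = 2, marker = marker), fixed_gates)
  se <- 100 * sqrt(0.15 * 0.85 / n)
  expect_lt(abs(m[["PIWI-HI"]] - 10), 4 * se + 1)   # +1 for tail leakage
  expect_lt(abs(m[["PIWI-LO"]] - 15), 4 * se + 1)
})

test_that("cell-cycle subfractions split at the 4C threshold", {
  expect_equal(cell_cycle_subfractions(data.frame(dna = rep(2, 8)), 3.5),
               c(pct_lt4C = 100, pct_4C = 0))
  set.seed(21)
  n <- 40000
  s_phase <- runif(n) < 0.6
  dna <- ifelse(s_phase, runif(n, 2, 3.5), rnorm(n, 4, 0.2))
  cc <- cell_cycle_subfractions(data.frame(dna = dna), 3.5)
  expect_equal(sum(cc), 100)
  expect_lt(abs(cc[["pct_lt4C"]] - 60), 1.5)
  expect_error(cell_cycle_subfractions(data.frame(dna = numeric()), 3.5),
               "empty")
})

test_that("fraction_change is plain percent change with a guarded baseline", {
  expect_equal(fraction_change(25, 25), 0)
  expect_equal(fraction_change(20, 30), 50)
  expect_equal(fraction_change(25, 10), -60)
  expect_error(fraction_change(0, 10), "positive")
})

test_that("gate calibration is deterministic and flags unsatisfiable criteria", {
  comp <- cell_composition()
  cfg <- sim_config(flow_events = 20000)
  wt <- simulate_flow_events(comp, cfg, seed = 30)
  irr <- simulate_flow_events(comp, cfg, irradiated = TRUE, seed = 31)
  g1 <- draw_gates(wt, irr)
  g2 <- draw_gates(wt, irr)
  expect_identical(g1, g2)
  # identical untreated/irradiated input cannot satisfy the depletion
  # criteria: the hinge penalty must be positive
  g3 <- draw_gates(wt, wt)
  expect_gt(g3$achieved$hinge_penalty, 0)
  # unimodal DNA structure (no cycling cells) cannot be calibrated
  flat <- wt; flat$dna <- rnorm(nrow(flat), 2, 0.1)
  expect_error(draw_gates(flat, flat), "bimodal")
  expect_error(draw_gates(wt[1:100, ], irr), "5000")
})

test_that("gating is invariant to event order and marker rescaling", {
  comp <- cell_composition()
  cfg <- sim_config(flow_events = 20000)
  wt <- simulate_flow_events(comp, cfg, seed = 32)
  irr <- simulate_flow_events(comp, cfg, irradiated = TRUE, seed = 33)
  g <- draw_gates(wt, irr)
  f <- quantify_fractions(wt, g)
  # permuting events changes nothing
  perm <- wt[sample(nrow(wt)), ]
  gp <- draw_gates(perm, irr)
  expect_equal(quantify_fractions(perm, gp), f)
  # multiplying marker units consistently changes thresholds, not fractions
  sc <- function(ev) { ev$marker <- ev$marker * 100; ev }
  gs <- draw_gates(sc(wt), sc(irr))
  expect_equal(quantify_fractions(sc(wt), gs), f, tolerance = 1e-9)
  expect_equal(marker_fractions(sc(wt), gs), marker_fractions(wt, g),
               tolerance = 0.5)
})

test_that("gate sets round-trip through JSON", {
  path <- file.path(tempdir(), "gates.json")
  write_gates(fixed_gates, path)
  g <- read_gates(path)
  expect_equal(g$theta_dna, fixed_gates$theta_dna)
  expect_equal(g$theta_hi, fixed_gates$theta_hi)
})
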