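universe10 <- sprintf("t%02d", 1:10)

test_that("fisher_overlap handles degenerate and disjoint inputs", {
  r <- fisher_overlap(universe10, universe10, universe10)
  expect_equal(r$a, 10)
  expect_equal(r$p_value, 1)
  r2 <- fisher_overlap(universe10[1:3], universe10[4:6], universe10)
  expect_equal(r2$a, 0)
  expect_equal(r2$odds_ratio, 0)
  expect_error(fisher_overlap(c("zz"), universe10[1:2], universe10),
               "contained in the universe")
})

test_that("one-sided p matches brute-force enumeration over draws", {
  A <- universe10[1:4]; B <- universe10[c(1:4, 9)]
  r <- fisher_overlap(A, B, universe10)
  # enumerate all C(10, 5) placements of B and count overlap >= 4
  draws <- combn(10, 5)
  hits <- mean(apply(draws, 2, function(d) length(intersect(d, 1:4)) >= 4))
  expect_equal(r$p_value, hits, tolerance = 1e-12)
  expect_equal(r$odds_ratio, Inf)  # b * c = 0 convention
})

test_that("two-sided alternative delegates to fisher.test", {
  A <- universe10[1:4]; B <- universe10[3:8]
  r <- fisher_overlap(A, B, universe10, alternative = "two.sided")
  ft <- fisher.test(matrix(c(2, 2, 4, 2), 2))
  expect_equal(r$p_value, ft$p.value)
})

test_that("signature profile reports exact percentages on toy sets", {
  sig <- structure(list(scheme = c("f1", "f2"),
                        members = list(f1 = universe10[1:4],
                                       f2 = universe10[5:7]),
                        fdr_cut = 0.05), class = "signature_set")
  dys <- structure(list(up = universe10[c(1, 2, 5)], down = universe10[3],
                        condition = "kd"), class = "dysregulation_sets")
  prof <- signature_dysregulation_profile(sig, dys, universe10)
  expect_equal(prof$pct_up, c(50, 100 / 3))
  expect_equal(prof$pct_down, c(25, 0))
  # dysregulation sets empty -> all zero
  dys0 <- structure(list(up = character(), down = character(),
                         condition = "null"), class = "dysregulation_sets")
  prof0 <- signature_dysregulation_profile(sig, dys0, universe10)
  expect_equal(prof0$pct_up, c(0, 0))
  # fully contained signature -> 100% up
  dys1 <- structure(list(up = universe10[1:4], down = character(),
                         condition = "all"), class = "dysregulation_sets")
  expect_equal(signature_dysregulation_profile(sig, dys1,
                                               universe10)$pct_up[1], 100)
  # empty signature -> warning and NA percentages
  sig$members$f2 <- character()
  expect_warning(pe <- signature_dysregulation_profile(sig, dys, universe10),
                 "empty set")
  expect_true(is.na(pe$pct_up[2]))
})

test_that("subcluster profile enforces universe containment", {
  tab <- data.frame(lineage = "L", subcluster = "s1")
  tab$enriched <- list(c(universe10[1:3], "not_in_universe"))
  dys <- structure(list(up = universe10[1], down = character(),
                        condition = "kd"), class = "dysregulation_sets")
  expect_error(subcluster_dysregulation_profile(tab, dys, universe10),
               "not contained")
})

test_that("state classification follows the two-threshold rule", {
  tab <- data.frame(lineage = "L",
                    subcluster = c("s1", "s2", "s3"),
                    piwi_level = c(100, 20, 0.5),
                    irr_frac = c(0.6, 0.2, 0.05))
  out <- classify_subcluster_states(tab)
  expect_equal(out$state, c("N/TS", "P", "M"))
  # overrides bypass the classifier entirely
  ov <- data.frame(lineage = "L", subcluster = c("s1", "s2", "s3"),
                   state = c("M", "M", "N/TS"))
  expect_equal(classify_subcluster_states(tab, overrides = ov)$state,
               c("M", "M", "N/TS"))
  # thresholds that identify no N/TS mark the lineage unassigned
  tab2 <- tab; tab2$piwi_level <- c(1, 1, 1) * 100
  tab2$irr_frac <- c(0.1, 0.1, 0.1)
  expect_warning(out2 <- classify_subcluster_states(
    tab2, piwi_high_frac = 2), "unassigned")
  expect_true(all(out2$state == "unassigned"))
})

test_that("lineage summary pools percentages and orders states", {
  prof <- data.frame(lineage = rep("L", 4),
                     subcluster = paste0("s", 1:4),
                     pct_up = c(5, 30, 40, 10), pct_down = c(5, 10, 0, 10),
                     state = c("N/TS", "P", "P", "M"))
  s <- lineage_profile_summary(prof)
  expect_equal(s$pooled$mean_pct[s$pooled$state == "N/TS"], 10)
  expect_equal(s$pooled$mean_pct[s$pooled$state == "P"], 40)
  expect_equal(s$pooled$mean_pct[s$pooled$state == "M"], 20)
  expect_equal(s$ordering_statistic, mean(c(40, 20)) - 10)
  # equal percentages give a zero ordering statistic
  prof$pct_up <- 10; prof$pct_down <- 0
  expect_equal(lineage_profile_summary(prof)$ordering_statistic, 0)
})
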