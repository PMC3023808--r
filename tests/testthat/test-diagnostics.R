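test_that("IST binning never splits equal counts and partitions the input", {
  # equal values stay together even past the minimum size
  one <- bin_by_ist(rep(1L, 400), min_bin_size = 200)
  expect_equal(nrow(one), 1L)
  expect_equal(one$weighted_mean_ist, 1.0)
  two <- bin_by_ist(rep(c(1L, 2L), c(250, 250)), min_bin_size = 200)
  expect_equal(two$n_interactions, c(250L, 250L))
  expect_equal(two$weighted_mean_ist, c(1.0, 2.0))
  expect_error(bin_by_ist(c(0L, 1L)), ">= 1")
  expect_warning(bin_by_ist(rep(2L, 10), min_bin_size = 200), "single bin")
  set.seed(41)
  for (i in 1:5) {
    ist <- 1L + stats::rpois(1000, 3)
    bins <- bin_by_ist(ist, min_bin_size = 150)
    members <- unlist(bins$members)
    expect_setequal(members, seq_along(ist))           # partition: union
    expect_equal(anyDuplicated(members), 0L)           # partition: disjoint
    expect_true(all(diff(bins$weighted_mean_ist) > 0)) # strictly increasing
    expect_true(all(bins$n_interactions >= 150))
  }
})

test_that("IST coverage hits the trivial bounds for containing/disjoint LC", {
  set.seed(42)
  ds <- interaction_dataset(paste0("A", 1:500), paste0("B", 1:500),
                            ist_count = 1L + stats::rpois(500, 2))
  all_cov <- ist_coverage_curve(ds, ds, min_bin_size = 100)
  expect_true(all(all_cov$lc_coverage == 1.0))
  none <- ist_coverage_curve(ds, interaction_dataset("Q", "R"),
                             min_bin_size = 100)
  expect_true(all(none$lc_coverage == 0.0))
})

test_that("binned log-log regression recovers a planted power law exactly", {
  papers <- rep(c(1, 4, 16, 64, 256), each = 6) # constant within each bin
  degree <- 2 * sqrt(papers)
  r <- suppressWarnings(binned_loglog_regression(papers, degree, bin_size = 6))
  expect_equal(r$slope, 0.5, tolerance = 1e-9)
  expect_equal(r$r_squared, 1, tolerance = 1e-9)
  expect_equal(r$n_bins, 5L)
  # any bin size that keeps bins homogeneous recovers the same exponent
  for (bs in c(2, 3)) {
    r2 <- suppressWarnings(binned_loglog_regression(papers, degree, bin_size = bs))
    expect_equal(r2$slope, 0.5, tolerance = 1e-9)
    expect_equal(r2$r_squared, 1, tolerance = 1e-9)
  }
  expect_error(binned_loglog_regression(c(1, 2), c(1, 2), bin_size = 1),
               "fewer than 3")
})

test_that("study-level regression is near zero when papers are independent of degree", {
  set.seed(43)
  world <- generate_world(n_proteins = 1000, n_true = 3000,
                          study_degree_correlation = 0)
  ds <- interaction_dataset(world$pair_a, world$pair_b)
  r <- degree_vs_study_regression(ds, world$study_levels)
  expect_lt(abs(r$slope), 0.1)
  # and clearly positive when the copula plants a correlation
  world2 <- generate_world(n_proteins = 1000, n_true = 3000,
                           study_degree_correlation = 0.8)
  ds2 <- interaction_dataset(world2$pair_a, world2$pair_b)
  r2 <- degree_vs_study_regression(ds2, world2$study_levels)
  expect_gt(r2$slope, 0.15)
})

test_that("HT coverage of the well-studied LC subset hits its trivial bounds", {
  fx <- micro_fixture()
  # ht identical to lc: full coverage at every cutoff
  tab <- ht_coverage_vs_cutoff(fx$lc, list(self = fx$lc), fx$levels,
                               cutoffs = c(50, 125))
  expect_true(all(tab$coverage == 1.0))
  # cutoff below every study level: the restriction is the whole dataset
  tab2 <- ht_coverage_vs_cutoff(fx$lc, list(X = fx$x), fx$levels,
                                cutoffs = 1)
  expect_equal(tab2$coverage,
               sum(ds_keys(fx$lc) %in% ds_keys(fx$x)) / ds_size(fx$lc))
})

test_that("the well-studied count curve is non-increasing with step positions", {
  lv <- study_levels(c(A = 10, B = 10, C = 50, D = 125, E = 300))
  curve <- well_studied_count_curve(lv, c(1, 10, 11, 50, 125, 126, 300, 301))
  expect_equal(curve$n_proteins, c(5L, 5L, 3L, 3L, 2L, 1L, 1L, 0L))
  set.seed(44)
  lv2 <- study_levels(stats::setNames(rpois(100, 80), paste0("G", 1:100)))
  c2 <- well_studied_count_curve(lv2, seq(1, 200, by = 7))
  expect_true(all(diff(c2$n_proteins) <= 0))
})

test_that("evidence enrichment matches the textbook chi-square and a null delta", {
  # identical datasets: zero delta, p-value 1
  fx <- micro_fixture()
  enr <- evidence_code_enrichment(fx$lc, fx$lc, codes = "Two-hybrid")
  expect_equal(enr$delta, 0)
  expect_equal(enr$p_value, 1)
  # hand-computed 2x2 chi-square without continuity correction:
  # 30/100 vs 60/100 carrying the code
  lc_all <- interaction_dataset(paste0("A", 1:100), paste0("B", 1:100),
                                evidence_codes = c(rep(list("Two-hybrid"), 30),
                                                   rep(list("FRET"), 70)))
  lc_ws <- interaction_dataset(paste0("A", 1:100), paste0("B", 1:100),
                               evidence_codes = c(rep(list("Two-hybrid"), 60),
                                                  rep(list("FRET"), 40)))
  enr2 <- evidence_code_enrichment(lc_all, lc_ws, codes = "Two-hybrid")
  # chi-square = sum over cells of (O-E)^2/E on the pooled 2x2 table
  p_hand <- stats::pchisq(200 * (60 * 70 - 40 * 30)^2 / (100 * 100 * 90 * 110),
                          df = 1, lower.tail = FALSE)
  expect_equal(enr2$p_value, p_hand, tolerance = 1e-9)
  expect_equal(enr2$delta, 0.3)
  expect_error(evidence_code_enrichment(fx$lc,
                                        interaction_dataset(character(0),
                                                            character(0))),
               "non-empty")
})

test_that("recuration proportions split scores into FP/TP classes", {
  scores <- data.frame(
    protein_a = paste0("A", 1:12), protein_b = paste0("B", 1:12),
    score = c(0, 0, 0, 0, 2, 2, 2, 2, 2, 1, 1, 1))
  # 4 FPs (1 involving WS), 5 TPs (2 involving WS); score-1 rows ignored
  r <- recuration_ws_proportions(scores, ws = c("A1", "A5", "B6"))
  expect_equal(r$fp_ws_fraction, 0.25)
  expect_equal(r$tp_ws_fraction, 0.4)
  expect_equal(c(r$n_fp, r$n_tp), c(4L, 5L))
  # no well-studied protein at all
  r0 <- recuration_ws_proportions(scores, ws = character(0))
  expect_equal(c(r0$fp_ws_fraction, r0$tp_ws_fraction), c(0, 0))
  expect_warning(
    recuration_ws_proportions(scores[scores$score == 2, ], "A1"),
    "empty recuration class")
})
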