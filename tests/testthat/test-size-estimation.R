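# brute-force oracle: the integer N whose hypergeometric mean overlap
# E[k | N] = n * m / N is closest to the observed k
brute_force_size <- function(n, m, k, n_max = 500) {
  grid <- seq.int(ceiling(max(n, m)), n_max)
  grid[which.min(abs(n * m / grid - k))]
}

test_that("the overlap estimator inverts consistent triples exactly", {
  expect_equal(estimate_size(100, 50, 25)$size, 200)
  set.seed(31)
  for (i in 1:25) {
    N <- sample(100:400, 1)
    # choose n, m with integer n * m / N
    n <- N / 2
    m <- sample(seq(10, N, by = 2), 1)
    k <- n * m / N
    if (k < 1 || k != round(k)) next
    expect_equal(estimate_size(n, m, k)$size, N)
  }
})

test_that("the estimator agrees with brute-force hypergeometric moment matching", {
  set.seed(32)
  for (i in 1:30) {
    N <- sample(60:500, 1)
    n <- sample(10:(N / 2), 1)
    m <- sample(10:(N / 2), 1)
    k <- max(1L, stats::rhyper(1, m, N - m, n))
    est <- estimate_size(n, m, k)$size
    bf <- brute_force_size(n, m, k, n_max = 4 * 500)
    # the continuous estimate and the integer argmin may differ by rounding
    expect_lt(abs(bf - est), 1 + 1e-9)
  }
})

test_that("the estimate is scale-equivariant and monotone in its components", {
  base <- estimate_size(500, 300, 20)$size
  expect_equal(estimate_size(1000, 300, 40)$size, base)
  expect_lt(estimate_size(500, 300, 25)$size, base)
  expect_gt(estimate_size(600, 300, 20)$size, base)
  expect_gt(estimate_size(500, 350, 20)$size, base)
})

test_that("degenerate and invalid inputs raise actionable errors", {
  expect_error(estimate_size(100, 50, 0), "unbounded")
  expect_error(estimate_size(0, 50, 5), "positive")
  expect_error(estimate_size(10, 10, 11), "exceed")
})

test_that("confidence intervals bracket the estimate and collapse when LC covers HT", {
  e <- estimate_size(2814, 1922.75, 144)
  for (m in c("transformed_overlap", "delta")) {
    ci <- confint(e, method = m)
    expect_lt(ci["lower"], e$size)
    expect_gt(ci["upper"], e$size)
  }
  # transformed interval is asymmetric: longer upper arm
  ci_t <- confint(e, method = "transformed_overlap")
  expect_gt(ci_t["upper"] - e$size, e$size - ci_t["lower"])
  # k = n: every HT true positive is in LC, m = N, zero variance
  e0 <- estimate_size(50, 200, 50)
  expect_equal(unname(confint(e0)), c(e0$size, e0$size))
  expect_error(confint(e, level = 1.2), "level")
})

test_that("the expanded parameter form matches the composed pipeline", {
  set.seed(33)
  for (i in 1:50) {
    ref_size <- sample(200:800, 1)
    ht_size <- sample(300:800, 1)
    fdr_ref <- runif(1, 0.05, 0.4)
    cov_ref <- runif(1, 0.1, 0.5)
    cov_ht <- runif(1, 0.1, min(0.5, cov_ref / (1 - fdr_ref) * 0.95))
    tp_lc <- sample(100:500, 1)
    k <- sample(5:15, 1)
    ref_pre <- cov_ref * ref_size
    ht_pre <- cov_ht * ht_size
    # composed route: chain the FDR, then Eq. 2 and the overlap estimate
    fdr_ht <- chain_fdr(cov_ht, cov_ref, fdr_ref)
    tp_ht <- ht_true_positives(ht_size, c(ht = ht_size), c(ht = fdr_ht))
    composed <- estimate_size(tp_ht, tp_lc, k)$size
    expanded <- estimate_size_expanded(ref_size * (1 - fdr_ref), tp_lc,
                                       ht_pre, ref_pre, k)$size
    expect_equal(expanded, composed, tolerance = 1e-9)
  }
  # degenerate single-dataset case: the expanded form is the plain estimator
  expect_equal(estimate_size_expanded(750, 300, 100, 100, 20)$size,
               estimate_size(750, 300, 20)$size)
  expect_error(estimate_size_expanded(750, 300, 100, 0, 20), "denominator")
})

test_that("the LC well-studied false-negative rate follows the TP accounting", {
  ht_ws <- interaction_dataset(paste0("A", 1:100), paste0("B", 1:100))
  lc_sup <- interaction_dataset(paste0("A", 1:100), paste0("B", 1:100))
  expect_equal(lc_ws_false_negative_rate(ht_ws, lc_sup, 0)$fnr, 0)
  lc20 <- interaction_dataset(paste0("A", 1:20), paste0("B", 1:20))
  r <- lc_ws_false_negative_rate(ht_ws, lc20, 0.2)
  expect_equal(r$tp_ht_ws, 80)
  expect_equal(r$fnr, 1 - 20 / 80)
  expect_error(lc_ws_false_negative_rate(ht_ws, lc20, 1), "zero")
})

test_that("the full pipeline reproduces hand arithmetic on the micro-fixture", {
  fx <- micro_fixture()
  fit <- run_full_estimation(fx$lc, fx$levels, fx$ht_list, ht = "X",
                             cutoff = 125, reference = "REF",
                             reference_fdr = 0.4)
  e <- fit$estimate
  expect_equal(ds_size(fit$lc_ws), 7L)
  expect_equal(ds_size(fit$unique_ws), 3L)
  expect_equal(e$tp_lc_ws, 7 - 0.35 * 3)
  expect_equal(e$tp_ht, 4 * (1 - 0.1), tolerance = 1e-12)
  expect_equal(e$tp_overlap, 2L)
  expect_equal(e$size, 3.6 * 5.95 / 2, tolerance = 1e-12)
  # union target: Eq. 2 component accounting over both screens
  fitu <- run_full_estimation(fx$lc, fx$levels, fx$ht_list, ht = "HT-Union",
                              cutoff = 125, reference = "REF",
                              reference_fdr = 0.4)
  expect_equal(fitu$estimate$tp_ht, 8 - (4 * 0.4 + 4 * 0.1),
               tolerance = 1e-12)
  expect_equal(fitu$estimate$tp_overlap, 3L)
  expect_equal(fitu$estimate$size, 6 * 5.95 / 3, tolerance = 1e-12)
  expect_equal(fit$report$quantity[7], "Estimated size")
})

test_that("cutoff sweep is constant when study levels sit above every cutoff", {
  fx <- micro_fixture()
  lv <- study_levels(stats::setNames(rep(500L, 8), c(LETTERS[1:8])))
  sw <- sweep_well_studied_cutoff(fx$lc, lv, fx$ht_list,
                                  cutoffs = c(100, 125, 150),
                                  datasets = "X", reference = "REF",
                                  reference_fdr = 0.4)
  expect_equal(length(unique(sw$size)), 1L)
})

test_that("the estimate decreases in the reference FDR; a singleton grid matches the fit", {
  fx <- micro_fixture()
  sw <- sweep_reference_fdr(fx$lc, fx$levels, fx$ht_list,
                            fdr_values = c(0.35, 0.4, 0.5),
                            datasets = "X", reference = "REF")
  expect_true(all(diff(sw$size) < 0))
  one <- sweep_reference_fdr(fx$lc, fx$levels, fx$ht_list,
                             fdr_values = 0.4, datasets = "X",
                             reference = "REF")
  fit <- run_full_estimation(fx$lc, fx$levels, fx$ht_list, ht = "X",
                             reference = "REF", reference_fdr = 0.4)
  expect_equal(one$size, fit$estimate$size, tolerance = 1e-12)
})

test_that("a zero-overlap sweep cell is flagged rather than fatal", {
  fx <- micro_fixture()
  # a dataset disjoint from LC yields no overlap at any cutoff
  ht_list <- c(fx$ht_list,
               list(Z = interaction_dataset(c("G", "H"), c("H", "G"))))
  sw <- sweep_well_studied_cutoff(fx$lc, fx$levels, ht_list,
                                  cutoffs = 125, datasets = c("X", "Z"),
                                  reference = "REF", reference_fdr = 0.4)
  expect_false(sw$flagged[sw$dataset == "X"])
  expect_true(sw$flagged[sw$dataset == "Z"])
  expect_true(is.na(sw$size[sw$dataset == "Z"]))
})

test_that("simulate draws overlap counts around the fitted expectation", {
  e <- estimate_size(500, 300, 30)
  k <- simulate(e, nsim = 400, seed = 9)
  expect_equal(mean(k), 30, tolerance = 0.1)
})
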