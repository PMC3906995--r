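test_that("binned fractions enumerate correctly and conserve cells", {
  b <- binned_fraction(c(1, 5, 5, 9), c(FALSE, TRUE, FALSE, TRUE), 4)
  expect_equal(b$n, c(1L, 2L, 1L))
  expect_equal(b$fraction, c(0, 0.5, 1))
  expect_equal(b$bin_lo, c(0, 4, 8))
  # all TRUE: every nonempty bin has fraction 1
  set.seed(1)
  x <- sample(0:30, 200, replace = TRUE)
  ba <- binned_fraction(x, rep(TRUE, 200), 4)
  expect_true(all(ba$fraction[ba$n > 0] == 1))
  expect_identical(sum(ba$n), 200L)
  # empty bins carry n = 0 and NA fraction
  be <- binned_fraction(c(1, 21), c(TRUE, TRUE), 4)
  expect_true(all(is.na(be$fraction[be$n == 0])))
  expect_error(binned_fraction(c(-1, 2), c(TRUE, TRUE), 4), "non-negative")
})

test_that("per-bin fractions agree with the binomial law on a generated cohort", {
  set.seed(2)
  n <- 5000L
  x <- sample(0:40, n, replace = TRUE)
  p <- 0.025 * x
  y <- runif(n) < p
  b <- binned_fraction(x, y, 4)
  for (i in seq_len(nrow(b))) {
    if (b$n[i] == 0) next
    sel <- x >= b$bin_lo[i] & x < b$bin_hi[i]
    p_gen <- mean(p[sel])
    ci <- qbinom(c(0.005, 0.995), b$n[i], p_gen) / b$n[i]
    expect_gte(b$fraction[i], ci[1])
    expect_lte(b$fraction[i], ci[2])
  }
})

test_that("robust fit: trivial, degenerate and recovery cases", {
  set.seed(3)
  x <- sample(0:40, 500, replace = TRUE)
  f0 <- robust_linear_fit(x, rep(FALSE, 500))
  expect_equal(f0$slope, 0, tolerance = 1e-10)
  expect_equal(f0$intercept, 0, tolerance = 1e-10)
  expect_error(robust_linear_fit(rep(5, 30), rbinom(30, 1, 0.5)), "degenerate")
  expect_error(robust_linear_fit(1:10, rep(c(TRUE, FALSE), 5)), ">= 20")
  # deterministic rank-quantile outcomes: parameter recovery
  N <- sample(0:40, 10000, replace = TRUE)
  y <- ave(seq_along(N), N, FUN = function(i)
    (rank(runif(length(i))) - 0.5) / length(i)) < 0.025 * N
  f <- robust_linear_fit(N, y)
  expect_lt(abs(f$slope / 0.025 - 1), 0.10)
  expect_lt(abs(f$intercept), 0.03)
  # gross outliers are resisted
  y2 <- as.numeric(y); y2[sample(10000, 100)] <- 50
  f2 <- robust_linear_fit(N, y2)
  expect_lt(abs(f2$slope / 0.025 - 1), 0.10)
})

test_that("robust fit agrees with the reference implementation on clean data", {
  skip_if_not_installed("MASS")
  set.seed(4)
  x <- runif(200, 0, 40)
  y <- 0.01 + 0.02 * x + rnorm(200, 0, 0.1)
  ours <- robust_linear_fit(x, y, c_tune = 4.685)
  ref <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-3)
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-3)
})

test_that("rank-sum test matches brute-force enumeration and the large-n limit", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2))$p_value, 1)
  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- sample(1:8, n1, replace = TRUE)  # ties included
    b <- sample(1:8, n2, replace = TRUE)
    expect_equal(rank_sum_test(a, b)$p_value, brute_force_ranksum_p(a, b))
  }
  # 8 vs 8: the tie-corrected normal approximation tracks the exact
  # enumeration closely (typical error well below 0.01, worst case
  # bounded by the lattice spacing of the exact distribution)
  errs <- vapply(1:10, function(i) {
    a <- rnorm(8); b <- rnorm(8, 0.3)
    abs(rank_sum_test(a, b)$p_value - fociPulse:::rank_sum_large(a, b))
  }, numeric(1))
  expect_lt(mean(errs), 0.01)
  expect_lt(max(errs), 0.025)
})

test_that("KS statistic equals the brute-force ECDF maximum", {
  expect_equal(ks_test(c(1, 2), c(3, 4))$D, 1)
  expect_equal(ks_test(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  set.seed(6)
  for (i in 1:25) {
    a <- rnorm(sample(5:40, 1))
    b <- rnorm(sample(5:40, 1), 0.4)
    expect_equal(ks_test(a, b)$D, brute_force_ks_D(a, b))
  }
  # asymptotic p sanity against the base implementation
  a <- rnorm(300); b <- rnorm(300, 0.2)
  expect_lt(abs(ks_test(a, b)$p_value -
                  suppressWarnings(stats::ks.test(a, b)$p.value)), 0.01)
})

test_that("proportions and their standard errors follow the closed form", {
  p <- proportion_with_se(50, 100)
  expect_equal(p$fraction, 0.5)
  expect_equal(p$se, 0.05)
  p2 <- proportion_with_se(25, 100)
  expect_equal(p2$se, sqrt(0.25 * 0.75 / 100))
  expect_equal(p2$se, 0.0433, tolerance = 1e-3)
  expect_warning(p0 <- proportion_with_se(0, 40), "degenerate")
  expect_equal(p0$se, 0)
  expect_error(proportion_with_se(3, 0), "positive")
  expect_error(proportion_with_se(5, 4), "0, n")
})

test_that("repeated-damage analysis handles strata and the memoryless null", {
  # independence: flags drawn independently, conditionals agree within 3 se
  set.seed(7)
  f1 <- runif(2000) < 0.4
  f2 <- runif(2000) < 0.25
  r <- repeated_damage_analysis(f1, f2)
  d <- abs(diff(r$conditional$fraction))
  se <- sqrt(sum(r$conditional$se^2))
  expect_lt(d, 3 * se)
  # responder-biased second response is detected
  bias <- ifelse(f1, 0.4, 0.1)
  f2b <- runif(2000) < bias
  rb <- repeated_damage_analysis(f1, f2b)
  expect_gt(rb$conditional$fraction[1] - rb$conditional$fraction[2],
            3 * sqrt(sum(rb$conditional$se^2)))
  # all first TRUE: the no-pulse stratum is NA, no crash
  expect_warning(
    re <- repeated_damage_analysis(rep(TRUE, 50), runif(50) < 0.5),
    "empty stratum")
  expect_true(is.na(re$conditional$fraction[2]))
  # stimulus comparison table appears when single-stimulus flags given
  rs <- repeated_damage_analysis(f1, f2, single_second_pulsed = runif(500) < 0.3)
  expect_identical(nrow(rs$stimulus_comparison), 2L)
})

test_that("cell-cycle classification: boundary, degenerate and mixture cases", {
  set.seed(8)
  # engineered intensities: the 99.5th percentile is ~1000 by design
  base <- c(runif(198, 100, 990), 995, 1000)
  cc <- classify_cell_cycle(c(base[1:198], 200, 330) * 1)
  # a cell at normalized 0.33 is S/G2 (boundary inclusive), 0.20 is G1
  norm <- cc$normalized_dapi
  expect_identical(as.character(cc$phase[norm < 0.33][1]), "G1")
  expect_true(all(cc$phase[norm >= 0.33] == "S/G2"))
  expect_error(classify_cell_cycle(runif(10)), ">= 50")
  expect_warning(cu <- classify_cell_cycle(rep(500, 100)), "unimodal")
  expect_true(all(cu$phase == "S/G2"))
  # bimodal mixture recovers the G1 weight
  cfg <- sim_config(n_cells = 2000, duration = 8, seed = 9)
  co <- simulate_cohort(cfg)
  cc2 <- classify_cell_cycle(co$cells$dapi_true)
  expect_lt(abs(mean(cc2$phase == "G1") - 0.7), 3 * sqrt(0.7 * 0.3 / 2000) + 0.015)
})
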