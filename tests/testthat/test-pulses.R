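test_that("trajectory normalization: scale invariance and baselines", {
  t <- seq(0, 24, by = 2 / 3)
  const <- rep(7, length(t))
  n <- normalize_trajectory(t, const, damage_time = 2)
  expect_equal(n$normalized, rep(1, length(t)))
  set.seed(1)
  lvl <- abs(rnorm(length(t), 100, 5))
  n1 <- normalize_trajectory(t, lvl, damage_time = 2)
  n2 <- normalize_trajectory(t, 7.3 * lvl, damage_time = 2)
  expect_equal(n1$normalized, n2$normalized)
  # no pre-damage frames: first three frames define the baseline
  n3 <- normalize_trajectory(t, lvl, damage_time = 0)
  expect_equal(n3$baseline, median(lvl[1:3]))
  expect_error(normalize_trajectory(t[1:5], lvl[1:5]), ">= 10")
  expect_error(normalize_trajectory(t, rep(0, length(t)), damage_time = 2),
               "baseline")
})

test_that("a pulse of amplitude 2x baseline normalizes to peak ~ 3", {
  set.seed(2)
  tr <- make_test_trajectory(8, noise_sd = 5)
  n <- normalize_trajectory(tr$times, tr$level, damage_time = 2)
  expect_equal(max(n$normalized), 3, tolerance = 0.2)
})

test_that("pulse calling: quiet baselines, canonical duration, determinism", {
  t <- seq(0, 24, by = 2 / 3)
  set.seed(3)
  flat <- normalize_trajectory(t, abs(rnorm(length(t), 100, 2)), damage_time = 2)
  expect_identical(call_pulses(flat$times, flat$normalized)$n_pulses, 0L)
  # canonical noiseless pulse: one call, duration within the 5-6 h range
  tr <- make_test_trajectory(8)
  n <- normalize_trajectory(tr$times, tr$level, damage_time = 2)
  pc <- call_pulses(n$times, n$normalized)
  expect_identical(pc$n_pulses, 1L)
  expect_gte(pc$pulses$duration, 5)
  expect_lte(pc$pulses$duration, 6)
  expect_identical(call_pulses(n$times, n$normalized)$pulses, pc$pulses)
  # trajectory shorter than min_width: flagged, zero pulses
  short <- call_pulses(c(0, 0.5, 1), c(1, 2, 1), min_width = 2)
  expect_identical(short$n_pulses, 0L)
  expect_identical(short$flag, "too-short")
})

test_that("three generated pulses are recovered with frame-level peak accuracy", {
  set.seed(4)
  t <- seq(0, 24, by = 2 / 3)
  good <- 0L
  for (i in 1:300) {
    onsets <- c(3, 10, 17)
    tr <- make_test_trajectory(onsets, noise_sd = 5)
    n <- normalize_trajectory(tr$times, tr$level, damage_time = 2)
    pc <- call_pulses(n$times, n$normalized)
    if (pc$n_pulses == 3L &&
        all(abs(pc$pulses$peak_time - (onsets + 2.75)) <= 2 / 3 + 1e-9))
      good <- good + 1L
  }
  expect_gte(good / 300, 0.95)
})

test_that("pulse calls are invariant under raw-trajectory rescaling", {
  set.seed(5)
  tr <- make_test_trajectory(c(5, 14), noise_sd = 4)
  n1 <- normalize_trajectory(tr$times, tr$level, damage_time = 2)
  n2 <- normalize_trajectory(tr$times, 11 * tr$level, damage_time = 2)
  expect_equal(call_pulses(n1$times, n1$normalized)$pulses,
               call_pulses(n2$times, n2$normalized)$pulses)
})

test_that("pulses are ordered and non-overlapping", {
  set.seed(6)
  for (i in 1:25) {
    tr <- make_test_trajectory(c(4, 9.5, 16), noise_sd = 5)
    n <- normalize_trajectory(tr$times, tr$level, damage_time = 2)
    p <- call_pulses(n$times, n$normalized)$pulses
    if (nrow(p) >= 2) {
      expect_true(all(diff(p$peak_time) > 0))
      expect_true(all(p$onset[-1] >= p$offset[-nrow(p)] - 1e-9))
    }
  }
})

test_that("subsequent-pulse analysis reads residual damage and the window", {
  t <- seq(0, 24, by = 2 / 3)
  foci <- round(30 * 2^(-t / 8))
  # single pulse: no subsequent pulse
  tr1 <- make_test_trajectory(4)
  n1 <- normalize_trajectory(tr1$times, tr1$level, damage_time = 2)
  p1 <- call_pulses(n1$times, n1$normalized)
  r1 <- subsequent_pulse_analysis(p1, t, foci, window = 8)
  expect_false(r1$has_subsequent)
  expect_equal(r1$breaks_after_pulse,
               foci[which.min(abs(t - p1$pulses$offset[1]))])
  # two pulses 5.5 h apart: subsequent within an 8 h window
  tr2 <- make_test_trajectory(c(4, 9.5))
  n2 <- normalize_trajectory(tr2$times, tr2$level, damage_time = 2)
  p2 <- call_pulses(n2$times, n2$normalized)
  expect_identical(p2$n_pulses, 2L)
  expect_true(subsequent_pulse_analysis(p2, t, foci, window = 8)$has_subsequent)
  # no pulses: the cell is rejected for this analysis
  flat <- call_pulses(t, rep(1, length(t)))
  expect_error(subsequent_pulse_analysis(flat, t, foci), "excluded")
})

test_that("amplitude and duration do not differ between damage groups", {
  # uniform-pulse property: low-damage vs high-damage cells produce
  # indistinguishable pulse shapes (the generator enforces excitability)
  cfg <- sim_config(pulse_slope = 1, n_evaluations = 1L, duration = 12,
                    seed = 1)
  t <- frame_times(cfg)
  set.seed(7)
  shapes <- lapply(c(2L, 35L), function(nb) {
    amps <- durs <- numeric(0)
    for (i in 1:250) {
      tr <- simulate_p53_trajectory(rep(nb, length(t)), cfg, times = t)
      n <- normalize_trajectory(t, tr$level, damage_time = cfg$damage_time)
      pc <- call_pulses(n$times, n$normalized)
      if (pc$n_pulses >= 1) {
        amps <- c(amps, pc$pulses$amplitude[1])
        durs <- c(durs, pc$pulses$duration[1])
      }
    }
    list(amps = amps, durs = durs)
  })
  expect_gt(rank_sum_test(shapes[[1]]$amps, shapes[[2]]$amps)$p_value, 0.01)
  expect_gt(rank_sum_test(shapes[[1]]$durs, shapes[[2]]$durs)$p_value, 0.01)
})
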