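test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(halflife_median = 0), "halflife_median")
  expect_error(sim_config(desensitization_factor = 1.5), "desensitization_factor")
  expect_error(sim_config(n_cells = 0), "n_cells")
  expect_error(sim_config(damage_time = 30, duration = 24), "damage_time")
})

test_that("break decay: degenerate inputs and basic contract", {
  t <- seq(0, 24, by = 2 / 3)
  expect_identical(simulate_break_decay(0, 6, t), integer(length(t)))
  expect_error(simulate_break_decay(5, -1, t), "halflife")
  expect_error(simulate_break_decay(5, 6, c(1, 2)), "start at 0")
  set.seed(1)
  for (i in 1:50) {
    s <- simulate_break_decay(sample(0:40, 1), runif(1, 1, 12), t)
    expect_identical(s[1L], s[1L])  # integer series
    expect_true(all(diff(s) <= 0))
    expect_true(all(s >= 0))
  }
})

test_that("break decay matches the binomial law at one half-life", {
  # at t = halflife each break survives independently w.p. 1/2, so the
  # total over 10,000 cells of n0 = 16 is Binomial(160000, 0.5)
  set.seed(2)
  n_rep <- 10000L
  tot <- sum(vapply(seq_len(n_rep), function(i)
    simulate_break_decay(16, 6, c(0, 6))[2L], integer(1)))
  ci <- qbinom(c(0.005, 0.995), 16L * n_rep, 0.5)
  expect_gte(tot, ci[1L])
  expect_lte(tot, ci[2L])
})

test_that("break decay survival curve stays within the DKW envelope", {
  # pooled per-break survival over 10,000 cells x 20 breaks is the ECDF
  # complement of iid exponential lifetimes; compare to 2^(-t/6)
  set.seed(3)
  t <- seq(0, 24, by = 2 / 3)
  n_rep <- 10000L
  n0 <- 20L
  acc <- numeric(length(t))
  for (i in seq_len(n_rep)) acc <- acc + simulate_break_decay(n0, 6, t)
  surv_hat <- acc / (n_rep * n0)
  eps <- sqrt(log(2 / 0.001) / (2 * n_rep * n0))  # DKW at alpha = 0.001
  expect_lt(max(abs(surv_hat - 2^(-t / 6))), eps)
})

test_that("p53 trajectory: trigger probability and excitability", {
  cfg <- sim_config(pulse_slope = 0.025, pulse_intercept = 0,
                    n_evaluations = 1L, duration = 12, seed = 1)
  t <- frame_times(cfg)
  # zero breaks, zero intercept: never triggers
  set.seed(4)
  tr <- simulate_p53_trajectory(integer(length(t)), cfg, times = t)
  expect_length(tr$pulse_times, 0L)
  # clamped probability 1: exactly one pulse at the single evaluation
  cfg1 <- cfg; cfg1$pulse_slope <- 1
  tr1 <- simulate_p53_trajectory(rep(5L, length(t)), cfg1, times = t)
  expect_length(tr1$pulse_times, 1L)
  expect_identical(tr1$pulse_times, cfg$damage_time)
  # binomial law at N = 20: p = 0.5, single evaluation
  set.seed(5)
  k <- sum(vapply(seq_len(10000L), function(i)
    length(simulate_p53_trajectory(rep(20L, length(t)), cfg, times = t)$pulse_times),
    integer(1)))
  ci <- qbinom(c(0.005, 0.995), 10000L, 0.5)
  expect_gte(k, ci[1L]); expect_lte(k, ci[2L])
})

test_that("pulse amplitude and duration are independent of break number", {
  # excitability: force a pulse (p = 1) at widely different N and regress
  # the detected amplitude on N
  cfg <- sim_config(pulse_slope = 1, pulse_intercept = 0,
                    n_evaluations = 1L, duration = 12, seed = 1)
  t <- frame_times(cfg)
  set.seed(6)
  res <- t(vapply(seq_len(500L), function(i) {
    n <- sample(1:40, 1)
    tr <- simulate_p53_trajectory(rep(n, length(t)), cfg, times = t)
    nt <- normalize_trajectory(t, tr$level, damage_time = cfg$damage_time)
    pc <- call_pulses(nt$times, nt$normalized)
    c(n = n, amp = if (pc$n_pulses >= 1) pc$pulses$amplitude[1L] else NA,
      dur = if (pc$n_pulses >= 1) pc$pulses$duration[1L] else NA)
  }, numeric(3)))
  res <- res[complete.cases(res), ]
  fit <- lm(amp ~ n, data = as.data.frame(res))
  ci <- confint(fit)["n", ]
  expect_true(ci[1L] < 0 && ci[2L] > 0)
  fit2 <- lm(dur ~ n, data = as.data.frame(res))
  ci2 <- confint(fit2)["n", ]
  expect_true(ci2[1L] < 0 && ci2[2L] > 0)
})

test_that("cohort: mean initial breaks obeys the stated law", {
  cfg <- sim_config(n_cells = 5000, dose_mean_breaks = 20, duration = 8,
                    seed = 7)
  co <- simulate_cohort(cfg)
  se <- sd(co$cells$n0_true) / sqrt(nrow(co$cells))
  expect_lt(abs(mean(co$cells$n0_true) - 20), 3 * se)
  # dose 0 forces n0 = 0 exactly
  cfg0 <- sim_config(n_cells = 100, dose_mean_breaks = 0, duration = 8, seed = 8)
  expect_true(all(simulate_cohort(cfg0)$cells$n0_true == 0L))
  expect_error(sim_config(n_cells = 0), "n_cells")
})

test_that("double-stimulus break series jump only at the re-damage frame", {
  cfg <- sim_config(n_cells = 30, dose_mean_breaks = 12, seed = 9)
  co <- simulate_cohort(cfg, protocol = "double", interval = 6)
  t2 <- cfg$damage_time + 6
  for (id in co$cells$cell_id) {
    r <- co$records[co$records$cell_id == id, ]
    up <- which(diff(r$foci_true) > 0)
    jump_times <- r$time_h[up + 1L]
    expect_true(all(jump_times %in% c(cfg$damage_time, t2)))
  }
})

test_that("identical configs reproduce identical cohorts", {
  cfg <- sim_config(n_cells = 25, duration = 8, seed = 10)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$cells, b$cells)
})

test_that("rendered stacks are deterministic and empty channels are quiet", {
  cfg <- sim_config(seed = 1)
  st <- data.frame(cell_id = 1, cy = 64, cx = 64, ry = 43, rx = 46,
                   n_foci = 0L, p53_level = 100)
  set.seed(11)
  a <- render_image_stack(st, cfg, image_size = 128)
  set.seed(11)
  b <- render_image_stack(st, cfg, image_size = 128)
  expect_identical(a$channels$foci, b$channels$foci)
  # 0 foci: no pixel rises far above background + diffuse signal + noise
  noise_sd <- sqrt(cfg$background + 0.1 * cfg$spot_peak + cfg$read_noise_sd^2)
  expect_lt(max(a$channels$foci),
            cfg$background + 0.1 * cfg$spot_peak + 6 * noise_sd)
})

test_that("crowded nuclei warn but still place spots", {
  cfg <- sim_config(seed = 1)
  set.seed(12)
  w <- capture_warnings(p <- place_foci(40, 30, 30, 12, 12, min_sep = 9))
  expect_gt(length(w), 0L)
  expect_match(w[1L], "minimum separation")
  expect_identical(nrow(p), 40L)
})

test_that("DAPI generator recovers the stated G1 fraction through the classifier", {
  cfg <- sim_config(n_cells = 2000, duration = 8, seed = 13)
  co <- simulate_cohort(cfg)
  cc <- classify_cell_cycle(co$cells$dapi_true)
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(mean(cc$phase == "G1") - 0.70), 3 * se + 0.02 * 0.7)
})
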