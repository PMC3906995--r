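# Shared fixtures, all generated in code.

# single centred nucleus rendered at a given spot count / SNR
render_test_nucleus <- function(n_foci, snr = 6, size = 128L, min_sep = 9,
                                cfg = sim_config(seed = 1)) {
  cfg$spot_peak <- snr * sqrt(cfg$background + cfg$read_noise_sd^2)
  st <- data.frame(cell_id = 1, cy = size / 2, cx = size / 2,
                   ry = 43, rx = 46, n_foci = n_foci, p53_level = 100)
  render_image_stack(st, cfg, image_size = size, min_sep = min_sep)
}

# noiseless synthetic trajectory with pulses at given onset times
make_test_trajectory <- function(pulse_onsets, times = seq(0, 24, by = 2 / 3),
                                 baseline = 100, amplitude = 2, duration = 5.5,
                                 noise_sd = 0) {
  bump <- numeric(length(times))
  for (p in pulse_onsets) bump <- bump + pulse_shape(times - p, duration, amplitude)
  lvl <- baseline * (1 + bump) + rnorm(length(times), 0, noise_sd)
  list(times = times, level = pmax(lvl, 0))
}

# independent brute-force rank-sum p-value: enumerate every assignment of
# the pooled observations to group A and compare absolute mean-rank shifts
brute_force_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  rk <- rank(pool)
  stat <- function(ix) sum(rk[ix])
  obs <- stat(seq_len(n1))
  center <- n1 * (length(pool) + 1) / 2
  combs <- utils::combn(length(pool), n1)
  vals <- apply(combs, 2L, stat)
  mean(abs(vals - center) >= abs(obs - center) - 1e-9)
}

# brute-force two-sample KS statistic over every pooled evaluation point
brute_force_ks_D <- function(a, b) {
  max(vapply(c(a, b), function(t) abs(mean(a <= t) - mean(b <= t)), numeric(1)))
}
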