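#' Canonical p53 pulse shape
#'
#' The stereotyped bump added to a trajectory when a pulse is triggered:
#' half-cosine rise and fall (`ramp` hours each) around a gently domed
#' top whose unique maximum (`amplitude`) sits at the pulse midpoint;
#' total support `duration` hours. Shape, amplitude and duration are
#' fixed — pulses are excitable, all-or-none events that do not scale
#' with the damage signal.
#'
#' @param tau time since pulse onset, hours (vectorized).
#' @param duration total pulse duration, hours.
#' @param amplitude peak height (multiples of basal level).
#' @param ramp rise/fall time, hours.
#' @param droop fractional dip of the dome at its edges relative to the
#'   peak.
#' @return bump value at `tau`, 0 outside `[0, duration]`.
#' @export
pulse_shape <- function(tau, duration = 5.5, amplitude = 2, ramp = 0.75,
                        droop = 0.2) {
  stopifnot(duration > 2 * ramp)
  out <- numeric(length(tau))
  up <- tau >= 0 & tau < ramp
  top <- tau >= ramp & tau <= duration - ramp
  down <- tau > duration - ramp & tau <= duration
  edge <- amplitude * (1 - droop)
  out[up] <- edge / 2 * (1 - cos(pi * tau[up] / ramp))
  u <- (tau[top] - duration / 2) / (duration / 2 - ramp)
  out[top] <- amplitude * (1 - droop * u^2)
  out[down] <- edge / 2 * (1 - cos(pi * (duration - tau[down]) / ramp))
  out
}

#' @keywords internal
evaluation_times <- function(cfg, damage_times) {
  evs <- lapply(damage_times, function(d) {
    k <- 0:ceiling(cfg$duration / cfg$evaluation_period)
    jit <- if (cfg$phase_jitter > 0) runif(1, 0, cfg$phase_jitter) else 0
    t <- d + k * cfg$evaluation_period + ifelse(k > 0, jit, 0)
    if (!is.null(cfg$n_evaluations)) t <- t[seq_len(min(length(t), cfg$n_evaluations))]
    t
  })
  # a later damage event restarts the evaluation clock
  if (length(damage_times) > 1L) {
    for (j in seq_len(length(evs) - 1L))
      evs[[j]] <- evs[[j]][evs[[j]] < damage_times[j + 1L]]
  }
  t <- sort(unique(unlist(evs)))
  t[t <= cfg$duration]
}

#' Simulate one cell's p53 reporter trajectory
#'
#' The damage signal is examined on an evaluation lattice anchored at
#' each damage event (period `cfg$evaluation_period`). At each
#' evaluation time `t` a pulse is triggered with probability
#' `clamp(pulse_intercept + pulse_slope * N(t), 0, 1) * sensitivity`,
#' multiplied by `cfg$desensitization_factor` when an *earlier* damage
#' stimulus lies within `cfg$desensitization_window` hours (the pathway
#' does not reset during the first phase of a response). A triggered
#' pulse adds the stereotyped bump of [pulse_shape()] — uniform amplitude
#' and duration, independent of `N(t)` — to a noisy basal level.
#'
#' @param break_series integer break counts aligned to `times`.
#' @param cfg a [sim_config()].
#' @param times frame time grid, hours (defaults to [frame_times()]).
#' @param damage_times times of damage stimuli, hours.
#' @param basal basal reporter level of this cell, au.
#' @param sensitivity per-cell sensitivity multiplier on the trigger
#'   probability.
#' @return list with `times`, `level` (raw au), `pulse_times` (triggered
#'   evaluation times, hours) and `triggered_at` (logical per evaluation
#'   time, named by time).
#' @export
simulate_p53_trajectory <- function(break_series, cfg, times = frame_times(cfg),
                                    damage_times = cfg$damage_time,
                                    basal = cfg$basal_p53_median,
                                    sensitivity = 1) {
  stopifnot(length(break_series) == length(times))
  evals <- evaluation_times(cfg, damage_times)
  pulse_times <- numeric(0)
  triggered <- logical(length(evals))
  for (i in seq_along(evals)) {
    t <- evals[i]
    n_t <- break_series[max(which(times <= t))]
    p <- clamp01(cfg$pulse_intercept + cfg$pulse_slope * n_t)
    p <- clamp01(p * sensitivity)
    earlier <- damage_times[damage_times < t]
    if (length(earlier) && any(t - earlier <= cfg$desensitization_window))
      p <- p * cfg$desensitization_factor
    if (runif(1) < p) {
      pulse_times <- c(pulse_times, t)
      triggered[i] <- TRUE
    }
  }
  bump <- numeric(length(times))
  for (t0 in pulse_times)
    bump <- bump + pulse_shape(times - t0, cfg$pulse_duration, cfg$pulse_amplitude)
  level <- basal * (1 + bump) + rnorm(length(times), 0, cfg$traj_noise_cv * basal)
  level <- pmax(level, 0)
  list(times = times, level = level, pulse_times = pulse_times,
       triggered_at = setNames(triggered, format(evals)))
}
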