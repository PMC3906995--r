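#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic single-cell
#' world: cohort size and dosing, per-cell repair heterogeneity, the
#' acquisition grid, the excitable p53 pulse mechanism, DNA-content
#' (DAPI) distribution, and the image-formation model.
#'
#' Defaults encode the acquisition used throughout: frames every 40
#' minutes for 24 hours, seven z-sections at 1 um steps, p53 pulses of
#' uniform shape lasting ~5.5 h, damage evaluations every 5.5 h anchored
#' at each damage event, and a pulse-trigger probability linear in the
#' current break number (slope 0.025 per focus calibrated so that ~50%
#' of cells carrying 20 breaks respond with a pulse).
#'
#' @param n_cells number of cells in the cohort.
#' @param dose_mean_breaks expected initial break number per cell.
#' @param break_dispersion negative-binomial size parameter for initial
#'   break counts; `Inf` (default) gives the Poisson limit.
#' @param n0_distribution `"negbin"` (default) or `"uniform"`; the latter
#'   draws initial breaks uniformly over `n0_range` (dose-series designs).
#' @param n0_range integer range for `n0_distribution = "uniform"`.
#' @param halflife_median median foci half-life, hours.
#' @param halflife_cv coefficient of variation of the log-normal half-life
#'   distribution.
#' @param frame_interval acquisition interval, minutes.
#' @param duration total imaging time, hours.
#' @param damage_time time of the (first) damage event, hours; frames
#'   before it provide the pre-stimulus baseline.
#' @param pulse_slope pulse-trigger probability per focus.
#' @param pulse_intercept baseline trigger probability.
#' @param pulse_duration duration of the stereotyped pulse, hours.
#' @param pulse_amplitude pulse amplitude as a multiple of the cell's
#'   basal p53 level.
#' @param evaluation_period hours between damage evaluations.
#' @param n_evaluations optional cap on the number of evaluation times per
#'   damage event (`NULL` = all that fit into `duration`).
#' @param phase_jitter if `> 0`, a per-cell uniform jitter (hours, at most
#'   this value) added to the evaluation lattice after the first
#'   evaluation of each damage event.
#' @param desensitization_factor multiplier in `[0, 1]` on the trigger
#'   probability for evaluations within `desensitization_window` hours
#'   after a preceding damage stimulus.
#' @param desensitization_window refractory window, hours.
#' @param sensitivity_cv coefficient of variation of a log-normal per-cell
#'   sensitivity multiplier (mean 1) on the trigger probability;
#'   0 = homogeneous cells.
#' @param basal_p53_median,basal_p53_cv basal reporter level (au) median
#'   and CV across cells.
#' @param traj_noise_cv frame-to-frame measurement noise on the p53
#'   trajectory, as a fraction of the basal level.
#' @param g1_fraction fraction of cells in G1 (2N DNA content).
#' @param dapi_scale arbitrary-unit scale of the DNA-content signal.
#' @param doublet_fraction fraction of bright doublet/debris DNA-content
#'   outliers anchoring the upper-percentile normalization.
#' @param background camera background level, photons.
#' @param photon_gain photons per intensity unit of the noiseless render.
#' @param read_noise_sd Gaussian read noise, photons.
#' @param spot_peak peak photon amplitude of a focus above background.
#' @param spot_sigma_px lateral Gaussian sigma of a rendered focus, px.
#' @param spot_sigma_z_um axial sigma of a rendered focus, um.
#' @param z_sections number of z-sections.
#' @param z_step_um z-step, um.
#' @param pixel_size_um pixel calibration, um.
#' @param nucleus_radius_px mean nucleus radius, px.
#' @param image_size field-of-view side, px (per-nucleus renders use a
#'   smaller window).
#' @param seed integer seed from which all cohort randomness flows.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_cells = 100L,
                       dose_mean_breaks = 20,
                       break_dispersion = Inf,
                       n0_distribution = c("negbin", "uniform"),
                       n0_range = c(0L, 40L),
                       halflife_median = 6,
                       halflife_cv = 0.4,
                       frame_interval = 40,
                       duration = 24,
                       damage_time = 2,
                       pulse_slope = 0.025,
                       pulse_intercept = 0,
                       pulse_duration = 5.5,
                       pulse_amplitude = 2,
                       evaluation_period = 5.5,
                       n_evaluations = NULL,
                       phase_jitter = 0,
                       desensitization_factor = 0.1,
                       desensitization_window = 6,
                       sensitivity_cv = 0,
                       basal_p53_median = 150,
                       basal_p53_cv = 0.4,
                       traj_noise_cv = 0.05,
                       g1_fraction = 0.7,
                       dapi_scale = 1000,
                       doublet_fraction = 0.02,
                       background = 100,
                       photon_gain = 1,
                       read_noise_sd = 2,
                       spot_peak = 60,
                       spot_sigma_px = 1.5,
                       spot_sigma_z_um = 1,
                       z_sections = 7L,
                       z_step_um = 1,
                       pixel_size_um = 0.11,
                       nucleus_radius_px = 45,
                       image_size = 256L,
                       seed = 1L) {
  n0_distribution <- match.arg(n0_distribution)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  pos <- c("halflife_median", "frame_interval", "duration", "pulse_duration",
           "evaluation_period", "dapi_scale", "photon_gain", "spot_sigma_px",
           "z_step_um", "pixel_size_um", "nucleus_radius_px")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(sprintf("`%s` must be > 0", f))
  nonneg <- c("dose_mean_breaks", "halflife_cv", "pulse_intercept",
              "pulse_amplitude", "sensitivity_cv", "traj_noise_cv",
              "background", "read_noise_sd", "spot_peak", "phase_jitter",
              "damage_time")
  for (f in nonneg)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
      stop(sprintf("`%s` must be >= 0", f))
  if (cfg$n_cells < 1L) stop("`n_cells` must be >= 1")
  if (cfg$desensitization_factor < 0 || cfg$desensitization_factor > 1)
    stop("`desensitization_factor` must lie in [0, 1]")
  if (cfg$g1_fraction < 0 || cfg$g1_fraction > 1)
    stop("`g1_fraction` must lie in [0, 1]")
  if (cfg$z_sections < 1L) stop("`z_sections` must be >= 1")
  if (cfg$damage_time >= cfg$duration)
    stop("`damage_time` must precede `duration`")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  cohort: %d cells, dose mean %.1f breaks (%s), seed %d\n",
              x$n_cells, x$dose_mean_breaks, x$n0_distribution, x$seed))
  cat(sprintf("  repair: half-life median %.1f h, CV %.2f\n",
              x$halflife_median, x$halflife_cv))
  cat(sprintf("  acquisition: every %d min for %.0f h, damage at %.1f h\n",
              as.integer(x$frame_interval), x$duration, x$damage_time))
  cat(sprintf("  pulses: p = clamp(%.3f + %.3f N), duration %.1f h, eval every %.1f h\n",
              x$pulse_intercept, x$pulse_slope, x$pulse_duration,
              x$evaluation_period))
  invisible(x)
}

#' Frame time grid of a configuration
#' @param cfg a `sim_config`.
#' @return numeric vector of frame times in hours, starting at 0.
#' @export
frame_times <- function(cfg) {
  seq(0, cfg$duration, by = cfg$frame_interval / 60)
}

#' @keywords internal
clamp01 <- function(p) pmin(1, pmax(0, p))
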