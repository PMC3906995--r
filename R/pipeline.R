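#' Pipeline configuration
#'
#' Bundles the simulation configuration with detection, pulse-calling
#' and statistics parameters, at one of two entry granularities:
#' `level = "counts"` feeds ground-truth break counts straight into the
#' statistical stages (fast; imaging skipped), `level = "images"`
#' renders per-cell image stacks and runs segmentation, tracking and
#' foci detection on them (full chain).
#'
#' @param sim a [sim_config()].
#' @param level `"counts"` or `"images"`.
#' @param protocol,interval,dose_means passed to [simulate_cohort()].
#' @param threshold_factor detection threshold multiplier.
#' @param sweep_factors optional factors for a robustness sweep.
#' @param detect detection parameters from [foci_params()].
#' @param min_prominence,min_width,min_separation,edge_frac pulse-caller
#'   parameters (see [call_pulses()]).
#' @param bin_width_foci,bin_width_halflife_h,bin_width_basal_au bin
#'   widths for the dose-response and covariate analyses (foci / hours /
#'   au).
#' @param alpha confidence level complement for regression bands.
#' @param dapi_cut G1 versus S/G2 boundary in normalized DNA-content
#'   units.
#' @param write_images if `TRUE` (image level), rendered foci stacks are
#'   saved as multi-page TIFFs under the output directory.
#' @param render_size per-cell render window, px (image level).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            level = c("counts", "images"),
                            protocol = "single", interval = 6,
                            dose_means = NULL,
                            threshold_factor = 1.0,
                            sweep_factors = NULL,
                            detect = foci_params(sim$spot_sigma_px),
                            min_prominence = 0.5, min_width = 2,
                            min_separation = 3, edge_frac = 0.1,
                            bin_width_foci = 4, bin_width_halflife_h = 2,
                            bin_width_basal_au = 50, alpha = 0.05,
                            dapi_cut = 0.33,
                            write_images = FALSE, render_size = 96L) {
  level <- match.arg(level)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON (or YAML)
#'
#' JSON is the native format; a `.yaml`/`.yml` file is accepted when the
#' `yaml` package is installed.
#'
#' @param path config file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the `yaml` package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  other <- raw[setdiff(names(raw), "sim")]
  do.call(pipeline_config, c(list(sim = sim), other))
}

#' Save a pipeline configuration as JSON
#' @param config a `pipeline_config`.
#' @param path output file.
#' @export
save_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
pulsed_in_window <- function(calls, lo, hi) {
  any(calls$pulses$onset >= lo & calls$pulses$onset < hi)
}

#' Run the full analysis pipeline
#'
#' Simulate -> (render/segment/track/detect at image level) -> normalize
#' and call pulses -> fit repair kinetics -> dose-response and covariate
#' statistics. Deterministic given the config seed; every stage's output
#' is persisted as CSV under `out_dir` together with a versioned JSON
#' summary and a log of every parameter used.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) a list with `cohort`, `foci` (per-cell per-frame
#'   counts used), `pulses`, `fits`, `stats`, `summary` and the paths
#'   written.
#' @export
run_pipeline <- function(config, out_dir = tempfile("focipulse_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("fociPulse pipeline log\n", file = logf)
  dump_params <- function(prefix, x) {
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v) && !inherits(v, "sim_config")) next
      if (inherits(v, "sim_config")) next
      log_line("%s%s = %s", prefix, nm, paste(format(v), collapse = ","))
    }
  }
  dump_params("config.", config)
  dump_params("config.sim.", config$sim)
  dump_params("config.detect.", config$detect)

  stage <- function(name, expr) {
    log_line("stage %s: start", name)
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    log_line("stage %s: done", name)
    r
  }
  sim <- config$sim
  cohort <- stage("simulate", simulate_cohort(
    sim, protocol = config$protocol, interval = config$interval,
    dose_means = config$dose_means))
  times <- frame_times(sim)
  d1 <- sim$damage_time

  if (config$level == "images") {
    foci_tab <- stage("detect", pipeline_detect_images(cohort, config, out_dir))
  } else {
    foci_tab <- cohort$records[, c("cell_id", "frame", "time_h")]
    foci_tab$foci_count <- cohort$records$foci_true
  }

  pulse_rows <- list()
  stage("call-pulses", {
    for (id in cohort$cells$cell_id) {
      r <- cohort$records[cohort$records$cell_id == id, ]
      nt <- normalize_trajectory(r$time_h, r$p53_au, damage_time = d1)
      calls <- call_pulses(nt$times, nt$normalized,
                           min_prominence = config$min_prominence,
                           min_width = config$min_width,
                           min_separation = config$min_separation,
                           edge_frac = config$edge_frac, cell_id = id)
      pulse_rows[[length(pulse_rows) + 1L]] <- data.frame(
        cell_id = id, n_pulses = calls$n_pulses,
        peak_times_h = paste(round(calls$pulses$peak_time, 3), collapse = ";"),
        durations_h = paste(round(calls$pulses$duration, 3), collapse = ";"),
        pulsed = pulsed_in_window(calls, d1 - 1, d1 + sim$evaluation_period - 1))
    }
  })
  pulses <- do.call(rbind, pulse_rows)

  fits <- stage("fit-repair",
                fit_repair(foci_tab, count_col = "foci_count", from_time = d1))

  stats <- stage("analyze", {
    cells <- cohort$cells
    n0_measured <- if (config$level == "images") {
      first_post <- min(times[times >= d1])
      m <- foci_tab[foci_tab$time_h == first_post, ]
      m$foci_count[match(cells$cell_id, m$cell_id)]
    } else cells$n0_true
    pulsed <- pulses$pulsed[match(cells$cell_id, pulses$cell_id)]
    bins <- binned_fraction(n0_measured, pulsed, config$bin_width_foci)
    fit <- if (length(unique(n0_measured)) > 1L && length(n0_measured) >= 20L)
      robust_linear_fit(n0_measured, pulsed, alpha = config$alpha) else NULL
    cc <- if (nrow(cells) >= 50L)
      classify_cell_cycle(cells$dapi_true, cut = config$dapi_cut) else NULL
    list(n0_measured = n0_measured, pulsed = pulsed, bins = bins, fit = fit,
         cell_cycle = cc)
  })

  write.csv(foci_tab, file.path(out_dir, "foci_counts.csv"), row.names = FALSE)
  write.csv(cohort$records, file.path(out_dir, "records.csv"), row.names = FALSE)
  write.csv(cohort$cells, file.path(out_dir, "cells_ground_truth.csv"),
            row.names = FALSE)
  write.csv(pulses, file.path(out_dir, "pulse_calls.csv"), row.names = FALSE)
  write.csv(fits, file.path(out_dir, "repair_fits.csv"), row.names = FALSE)
  write.csv(stats$bins, file.path(out_dir, "binned_fraction.csv"),
            row.names = FALSE)

  summary <- list(
    schema_version = "1.0",
    seed = sim$seed, n_cells = sim$n_cells, level = config$level,
    protocol = config$protocol,
    pulse_fraction = mean(stats$pulsed),
    dose_response = list(
      bin_width_foci = config$bin_width_foci,
      bins = stats$bins,
      slope = if (!is.null(stats$fit)) stats$fit$slope else NA,
      intercept = if (!is.null(stats$fit)) stats$fit$intercept else NA,
      se_slope = if (!is.null(stats$fit)) stats$fit$se_slope else NA,
      alpha = config$alpha,
      robust_variant = "IRLS Tukey bisquare, asymptotic covariance band"),
    g1_fraction = if (!is.null(stats$cell_cycle))
      mean(stats$cell_cycle$phase == "G1") else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  log_line("pipeline complete")
  invisible(list(cohort = cohort, foci = foci_tab, pulses = pulses,
                 fits = fits, stats = stats, summary = summary,
                 out_dir = out_dir))
}

#' @keywords internal
pipeline_detect_images <- function(cohort, config, out_dir) {
  # image-level chain on per-cell static nucleus windows: render each
  # frame, segment + track on the nuclear channel, enumerate foci.
  sim <- config$sim
  times <- frame_times(sim)
  size <- as.integer(config$render_size)
  img_dir <- file.path(out_dir, "images")
  if (config$write_images) dir.create(img_dir, showWarnings = FALSE)
  rows <- list()
  for (id in cohort$cells$cell_id) {
    r <- cohort$records[cohort$records$cell_id == id, ]
    r <- r[order(r$frame), ]
    rad <- sim$nucleus_radius_px
    state0 <- data.frame(cell_id = id, cy = size / 2, cx = size / 2,
                         ry = rad * 0.95, rx = rad * 1.05,
                         n_foci = 0L, p53_level = 0)
    masks <- vector("list", nrow(r))
    counts <- integer(nrow(r))
    for (k in seq_len(nrow(r))) {
      st <- state0
      st$n_foci <- r$foci_true[k]
      st$p53_level <- r$p53_au[k]
      stk <- render_image_stack(st, sim, timepoint = r$frame[k],
                                image_size = size)
      if (config$write_images)
        write_tiff(stk$channels$foci,
                   file.path(img_dir, sprintf("cell%03d_t%03d_foci.tif", id, k)),
                   description = sprintf("seed=%d;cell=%d;frame=%d",
                                         sim$seed, id, r$frame[k]))
      seg <- segment_nuclei(max_project(stk$channels$h2b))
      masks[[k]] <- seg
      proj <- max_project(stk$channels$foci)
      det <- detect_foci(proj, seg, threshold_factor = config$threshold_factor,
                         params = config$detect)
      counts[k] <- if (nrow(det$counts)) sum(det$counts$count) else 0L
    }
    if (nrow(r) >= 2L) {
      trk <- track_nuclei(masks)
      if (length(unique(trk$cell_id[trk$frame > 0])) > nrow(r) * 1.5)
        warning(sprintf("cell %d: unstable track", id))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = id, frame = r$frame, time_h = r$time_h, foci_count = counts)
  }
  do.call(rbind, rows)
}
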