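#' Segment nuclei from a nuclear-marker image
#'
#' Automated thresholding and watershed segmentation of the H2B signal:
#' Gaussian smoothing, Otsu threshold, hole filling, a minimum-area
#' floor, and splitting of touching nuclei by watershed on the inverted
#' Euclidean distance transform seeded at its smoothed local maxima.
#'
#' @param h2b 2D numeric matrix (nuclear-marker channel, >= 64 x 64 px).
#' @param min_area minimum object area, px.
#' @param smooth_sigma pre-threshold smoothing, px.
#' @param seed_min_distance minimum separation between watershed seeds,
#'   px; roughly the smallest expected nucleus radius.
#' @return an object of class `nucleus_mask`: integer `labels` matrix
#'   plus a per-nucleus table (`label`, `area_px`, bounding box,
#'   centroid).
#' @export
segment_nuclei <- function(h2b, min_area = 200L, smooth_sigma = 2,
                           seed_min_distance = 15L) {
  if (nrow(h2b) < 64L || ncol(h2b) < 64L)
    stop("image must be at least 64 x 64 px")
  sm <- gaussian_blur(h2b, smooth_sigma)
  thr <- otsu_threshold(sm)
  fg <- sm > thr
  # blank-image guard: demand real foreground/background contrast, not
  # just an Otsu split of the noise distribution
  if (!any(fg) || !any(!fg) ||
      (mean(sm[fg]) - mean(sm[!fg])) < 3 * sd(sm[!fg]))
    return(new_nucleus_mask(matrix(0L, nrow(h2b), ncol(h2b))))
  fg <- fill_holes(fg)
  dt <- distance_transform(fg)
  dts <- gaussian_blur(dt, 2)
  seeds <- local_maxima(dts, fg, min_distance = seed_min_distance,
                        threshold = 2)
  if (nrow(seeds) == 0L) return(new_nucleus_mask(matrix(0L, nrow(h2b), ncol(h2b))))
  markers <- matrix(0L, nrow(h2b), ncol(h2b))
  markers[cbind(seeds$y, seeds$x)] <- seq_len(nrow(seeds))
  lab <- watershed(-dts, markers, fg)
  # drop small objects, relabel contiguously
  sizes <- tabulate(lab, max(lab))
  keep <- which(sizes >= min_area)
  remap <- integer(max(lab) + 1L)
  remap[keep + 1L] <- seq_along(keep)
  lab <- matrix(remap[lab + 1L], nrow(lab), ncol(lab))
  new_nucleus_mask(lab)
}

#' @keywords internal
new_nucleus_mask <- function(labels) {
  n <- max(labels)
  tab <- if (n > 0L) {
    do.call(rbind, lapply(seq_len(n), function(l) {
      w <- which(labels == l, arr.ind = TRUE)
      data.frame(label = l, area_px = nrow(w),
                 y_min = min(w[, 1L]), y_max = max(w[, 1L]),
                 x_min = min(w[, 2L]), x_max = max(w[, 2L]),
                 cy = mean(w[, 1L]), cx = mean(w[, 2L]))
    }))
  } else {
    data.frame(label = integer(0), area_px = integer(0), y_min = integer(0),
               y_max = integer(0), x_min = integer(0), x_max = integer(0),
               cy = numeric(0), cx = numeric(0))
  }
  structure(list(labels = labels, nuclei = tab), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d nuclei in %d x %d px\n",
              nrow(x$nuclei), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Detection parameters for foci enumeration
#'
#' @param spot_sigma_px expected focus sigma, px; also the Canny
#'   smoothing sigma.
#' @param tophat_radius structuring-element radius for the white top-hat;
#'   default about twice the expected spot diameter.
#' @param canny_quantiles hysteresis thresholds as intensity-percentile
#'   pair inside the nucleus.
#' @param close_radius radius used to close Canny contours.
#' @param min_distance minimum separation of focus seeds, px.
#' @param noise_floor_k seeds must also exceed the nucleus median by this
#'   many robust noise standard deviations (estimated from the negative
#'   half-distribution of the smoothed top-hat).
#' @return list of detection parameters.
#' @export
foci_params <- function(spot_sigma_px = 1.5,
                        tophat_radius = NULL,
                        canny_quantiles = c(0.70, 0.90),
                        close_radius = 2L,
                        min_distance = NULL,
                        noise_floor_k = 5) {
  if (is.null(tophat_radius))
    tophat_radius <- ceiling(2 * 2.355 * spot_sigma_px / 2) + 1L
  if (is.null(min_distance))
    min_distance <- max(2L, round(1.5 * spot_sigma_px))
  list(spot_sigma_px = spot_sigma_px, tophat_radius = tophat_radius,
       canny_quantiles = canny_quantiles, close_radius = close_radius,
       min_distance = min_distance, noise_floor_k = noise_floor_k)
}

#' Enumerate 53BP1 foci per nucleus
#'
#' Per nucleus: (1) white top-hat to remove background larger than the
#' expected spot, (2) Canny edge map of the top-hat image, (3)
#' morphological closing and hole filling of the edge contours into
#' candidate regions, (4) local maxima of the smoothed top-hat inside
#' the candidate mask are retained as foci when their peak intensity
#' reaches `threshold_factor` times the Otsu ("optimal") threshold of
#' the top-hat intensities within the nucleus, and (5) a
#' marker-directed watershed from the retained maxima assigns pixels of
#' touching candidates to individual foci. The count is the number of
#' retained maxima, which makes counts monotone non-increasing in
#' `threshold_factor`.
#'
#' @param foci_proj 2D maximum projection of the foci channel.
#' @param mask a `nucleus_mask` from [segment_nuclei()], or an integer
#'   label matrix.
#' @param threshold_factor multiplier on the optimal (Otsu) threshold.
#' @param params detection parameters from [foci_params()].
#' @return an object of class `foci_set`: data.frame `foci` (`nucleus`,
#'   `y`, `x`, `peak_intensity`, `integrated_intensity`) and data.frame
#'   `counts` (`nucleus`, `count`, `threshold_factor`).
#' @export
detect_foci <- function(foci_proj, mask, threshold_factor = 1.0,
                        params = foci_params()) {
  pre <- prepare_foci_detection(foci_proj, mask, params)
  threshold_foci(pre, threshold_factor, params)
}

#' @keywords internal
prepare_foci_detection <- function(foci_proj, mask, params = foci_params()) {
  labels <- if (inherits(mask, "nucleus_mask")) mask$labels else mask
  stopifnot(all(dim(labels) == dim(foci_proj)))
  n_nuc <- max(labels)
  out <- vector("list", n_nuc)
  se <- params$tophat_radius
  for (l in seq_len(n_nuc)) {
    w <- which(labels == l, arr.ind = TRUE)
    if (nrow(w) < (2 * se + 1)^2) {
      warning(sprintf("nucleus %d smaller than the structuring element; count 0", l))
      out[[l]] <- list(label = l, empty = TRUE)
      next
    }
    y0 <- max(1L, min(w[, 1L]) - se); y1 <- min(nrow(labels), max(w[, 1L]) + se)
    x0 <- max(1L, min(w[, 2L]) - se); x1 <- min(ncol(labels), max(w[, 2L]) + se)
    crop <- foci_proj[y0:y1, x0:x1, drop = FALSE]
    nmask <- labels[y0:y1, x0:x1, drop = FALSE] == l
    th <- white_tophat(crop, se)
    edges <- canny_edges(th, sigma = params$spot_sigma_px,
                         low = NULL, high = NULL, mask = nmask)
    # matched filter: smooth the top-hat at the expected spot scale
    ths <- gaussian_blur(th, params$spot_sigma_px)
    otsu <- otsu_threshold(ths[nmask])
    # candidate regions: closed+filled edge contours, plus bright cores
    # the contours may miss in crowded nuclei
    cand <- (fill_holes(im_close(edges * 1, params$close_radius) > 0) |
               (ths >= otsu)) & nmask
    # noise floor: within-nucleus baseline (median; robust to moderate
    # spot coverage) plus the camera noise scale estimated outside the
    # nucleus, where no spots can inflate it
    bg <- ths[!nmask]
    if (length(bg) < 50L) bg <- ths
    floor_thr <- median(ths[nmask]) + params$noise_floor_k * mad(bg)
    peaks <- local_maxima(ths, cand, min_distance = params$min_distance,
                          threshold = 0)
    out[[l]] <- list(label = l, empty = FALSE, y0 = y0, x0 = x0,
                     tophat = th, smooth = ths, cand = cand, nmask = nmask,
                     peaks = peaks, otsu = otsu, floor = floor_thr)
  }
  structure(list(nuclei = out, dim = dim(labels)), class = "foci_detection")
}

#' @keywords internal
threshold_foci <- function(pre, threshold_factor, params = foci_params()) {
  foci <- list()
  counts <- data.frame(nucleus = integer(0), count = integer(0),
                       threshold_factor = numeric(0))
  for (nuc in pre$nuclei) {
    l <- nuc$label
    if (isTRUE(nuc$empty)) {
      counts <- rbind(counts, data.frame(nucleus = l, count = 0L,
                                         threshold_factor = threshold_factor))
      next
    }
    thr <- max(threshold_factor * nuc$otsu, nuc$floor)
    keep <- nuc$peaks[nuc$peaks$value >= thr, , drop = FALSE]
    cnt <- nrow(keep)
    counts <- rbind(counts, data.frame(nucleus = l, count = cnt,
                                       threshold_factor = threshold_factor))
    if (cnt > 0L) {
      markers <- matrix(0L, nrow(nuc$tophat), ncol(nuc$tophat))
      markers[cbind(keep$y, keep$x)] <- seq_len(cnt)
      regions <- watershed(-nuc$smooth, markers, nuc$cand)
      integ <- vapply(seq_len(cnt),
                      function(j) sum(nuc$tophat[regions == j]), numeric(1))
      foci[[length(foci) + 1L]] <- data.frame(
        nucleus = l,
        y = keep$y + nuc$y0 - 1L, x = keep$x + nuc$x0 - 1L,
        peak_intensity = keep$value, integrated_intensity = integ)
    }
  }
  foci <- if (length(foci)) do.call(rbind, foci) else
    data.frame(nucleus = integer(0), y = integer(0), x = integer(0),
               peak_intensity = numeric(0), integrated_intensity = numeric(0))
  structure(list(foci = foci, counts = counts,
                 threshold_factor = threshold_factor), class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat(sprintf("<foci_set> %d foci in %d nuclei (threshold factor %.2f)\n",
              nrow(x$foci), nrow(x$counts), x$threshold_factor))
  invisible(x)
}

#' Foci counts across a sweep of detection thresholds
#'
#' Re-applies [detect_foci()]'s final thresholding step over a grid of
#' factors (the expensive top-hat/Canny/maxima stages are computed once),
#' quantifying the robustness of the enumeration to the threshold
#' choice. Counts are monotone non-increasing in the factor.
#'
#' @inheritParams detect_foci
#' @param factors positive multipliers of the optimal threshold
#'   (default the 0.6-1.3 range used for the robustness analysis; the
#'   wider 0.3-1.6 range described elsewhere can be supplied instead).
#' @return list with `counts` (data.frame `nucleus` x `threshold_factor`)
#'   and `summary` (per-nucleus mean, sd and range of counts).
#' @export
threshold_sweep <- function(foci_proj, mask,
                            factors = seq(0.6, 1.3, by = 0.175),
                            params = foci_params()) {
  stopifnot(all(factors > 0))
  pre <- prepare_foci_detection(foci_proj, mask, params)
  counts <- do.call(rbind, lapply(factors, function(f)
    threshold_foci(pre, f, params)$counts))
  agg <- split(counts$count, counts$nucleus)
  summary <- data.frame(
    nucleus = as.integer(names(agg)),
    mean_count = vapply(agg, mean, numeric(1)),
    sd_count = vapply(agg, sd, numeric(1)),
    min_count = vapply(agg, min, numeric(1)),
    max_count = vapply(agg, max, numeric(1))
  )
  rownames(summary) <- NULL
  list(counts = counts, summary = summary, factors = factors)
}
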