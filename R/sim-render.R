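#' @keywords internal
ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  yy <- matrix(seq_len(nr), nr, nc)
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

#' Place foci inside a nucleus with a minimum pairwise separation
#'
#' Rejection sampling inside the ellipse (keeping a margin from the rim);
#' when the nucleus cannot accommodate the requested count at the given
#' separation, a warning is emitted and the focus is placed anyway after
#' the retry budget is exhausted.
#'
#' @param n number of foci.
#' @param cy,cx,ry,rx nucleus ellipse (px).
#' @param min_sep minimum pairwise distance (px).
#' @param margin distance kept from the nucleus rim (px).
#' @param max_tries rejection retries per focus.
#' @return data.frame with `y`, `x` (px, continuous).
#' @export
place_foci <- function(n, cy, cx, ry, rx, min_sep = 6, margin = 3,
                       max_tries = 200L) {
  ys <- xs <- numeric(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      a <- runif(1, 0, 2 * pi)
      r <- sqrt(runif(1))
      y <- cy + r * (ry - margin) * sin(a)
      x <- cx + r * (rx - margin) * cos(a)
      if (!length(ys) || min((ys - y)^2 + (xs - x)^2) >= min_sep^2) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      warning(sprintf("focus %d placed below the minimum separation (nucleus too crowded)", i))
    ys <- c(ys, y)
    xs <- c(xs, x)
  }
  data.frame(y = ys, x = xs)
}

#' @keywords internal
add_gaussian_spot <- function(vol, y0, x0, z0, amp, sigma_xy, sigma_z) {
  nz <- dim(vol)[1L]; nr <- dim(vol)[2L]; nc <- dim(vol)[3L]
  r <- ceiling(4 * sigma_xy)
  ys <- max(1L, floor(y0 - r)):min(nr, ceiling(y0 + r))
  xs <- max(1L, floor(x0 - r)):min(nc, ceiling(x0 + r))
  gy <- exp(-(ys - y0)^2 / (2 * sigma_xy^2))
  gx <- exp(-(xs - x0)^2 / (2 * sigma_xy^2))
  patch <- outer(gy, gx)
  for (z in seq_len(nz)) {
    gz <- exp(-(z - z0)^2 / (2 * sigma_z^2))
    vol[z, ys, xs] <- vol[z, ys, xs] + amp * gz * patch
  }
  vol
}

#' @keywords internal
apply_camera_noise <- function(photons, cfg) {
  noisy <- rpois(length(photons), lambda = pmax(photons, 0)) +
    rnorm(length(photons), 0, cfg$read_noise_sd)
  array(pmax(noisy, 0), dim = dim(photons))
}

#' Render a multi-channel image stack for one timepoint
#'
#' Produces the synthetic acquisition: an H2B nuclear channel (filled
#' textured ellipses, single section), a 53BP1 foci channel (3D Gaussian
#' spots across `cfg$z_sections` sections plus diffuse nuclear
#' background), and a p53 reporter channel (nuclear intensity
#' proportional to the cell's p53 level). Poisson photon noise followed
#' by Gaussian read noise is applied per channel.
#'
#' @param state per-cell state at this timepoint: data.frame with columns
#'   `cell_id`, `cy`, `cx`, `ry`, `rx` (nucleus ellipse, px), `n_foci`,
#'   `p53_level` (au), and optionally `h2b_level`.
#' @param cfg a [sim_config()].
#' @param timepoint frame index stored in the result.
#' @param image_size field side in px (default `cfg$image_size`).
#' @param min_sep minimum focus separation in px (default
#'   `4 * cfg$spot_sigma_px`).
#' @return an object of class `image_stack`: channels `h2b` (matrix),
#'   `foci` (z, y, x array), `p53` (matrix); pixel/z calibration; and
#'   `truth` (the input state plus the list of true focus centroids).
#' @export
render_image_stack <- function(state, cfg, timepoint = 1L,
                               image_size = cfg$image_size,
                               min_sep = 4 * cfg$spot_sigma_px) {
  stopifnot(all(c("cell_id", "cy", "cx", "ry", "rx", "n_foci", "p53_level")
                %in% names(state)))
  nr <- nc <- as.integer(image_size)
  nz <- as.integer(cfg$z_sections)
  if (is.null(state$h2b_level)) state$h2b_level <- 120
  h2b <- matrix(0, nr, nc)
  p53 <- matrix(0, nr, nc)
  foci_vol <- array(0, dim = c(nz, nr, nc))
  sigma_z_px <- cfg$spot_sigma_z_um / cfg$z_step_um
  centroids <- vector("list", nrow(state))
  for (i in seq_len(nrow(state))) {
    s <- state[i, ]
    m <- ellipse_mask(nr, nc, s$cy, s$cx, s$ry, s$rx)
    texture <- 1 + 0.12 * gaussian_blur(matrix(rnorm(nr * nc), nr, nc), 3)
    h2b[m] <- h2b[m] + s$h2b_level * texture[m]
    p53[m] <- p53[m] + s$p53_level * texture[m]
    # diffuse unbound 53BP1 in the nucleoplasm
    for (z in seq_len(nz)) {
      sl <- foci_vol[z, , ]
      sl[m] <- sl[m] + 0.1 * cfg$spot_peak
      foci_vol[z, , ] <- sl
    }
    if (s$n_foci > 0) {
      pos <- place_foci(s$n_foci, s$cy, s$cx, s$ry, s$rx, min_sep = min_sep)
      pos$z <- runif(s$n_foci, (nz + 1) / 2 - 1, (nz + 1) / 2 + 1)
      for (j in seq_len(nrow(pos)))
        foci_vol <- add_gaussian_spot(foci_vol, pos$y[j], pos$x[j], pos$z[j],
                                      cfg$spot_peak, cfg$spot_sigma_px, sigma_z_px)
      centroids[[i]] <- data.frame(cell_id = s$cell_id, y = pos$y, x = pos$x)
    }
  }
  gain <- cfg$photon_gain
  out <- list(
    channels = list(
      h2b = apply_camera_noise(cfg$background + gain * h2b, cfg),
      foci = apply_camera_noise(cfg$background + gain * foci_vol, cfg),
      p53 = apply_camera_noise(cfg$background + gain * p53, cfg)
    ),
    pixel_size_um = cfg$pixel_size_um, z_step_um = cfg$z_step_um,
    timepoint = as.integer(timepoint),
    truth = list(state = state, foci = do.call(rbind, centroids))
  )
  class(out) <- "image_stack"
  out
}

#' @export
print.image_stack <- function(x, ...) {
  dims <- dim(x$channels$foci)
  cat(sprintf("<image_stack> t=%d, foci channel %d z x %d x %d px, %d nuclei\n",
              x$timepoint, dims[1L], dims[2L], dims[3L], nrow(x$truth$state)))
  invisible(x)
}

#' Random nucleus layout for a rendered field
#'
#' Places `n` non-overlapping elliptical nuclei uniformly in the field.
#'
#' @param n number of nuclei.
#' @param cfg a [sim_config()].
#' @param image_size field side, px.
#' @return data.frame with `cell_id`, `cy`, `cx`, `ry`, `rx`.
#' @export
layout_nuclei <- function(n, cfg, image_size = cfg$image_size) {
  rad <- cfg$nucleus_radius_px
  cys <- cxs <- rys <- rxs <- numeric(0)
  for (i in seq_len(n)) {
    for (k in seq_len(500L)) {
      ry <- rad * runif(1, 0.8, 1.2)
      rx <- rad * runif(1, 0.8, 1.2)
      cy <- runif(1, ry + 2, image_size - ry - 2)
      cx <- runif(1, rx + 2, image_size - rx - 2)
      if (!length(cys) ||
          min(sqrt((cys - cy)^2 + (cxs - cx)^2) - (rys + ry)) > 4)
        break
    }
    cys <- c(cys, cy); cxs <- c(cxs, cx); rys <- c(rys, ry); rxs <- c(rxs, rx)
  }
  data.frame(cell_id = seq_len(n), cy = cys, cx = cxs, ry = rys, rx = rxs)
}
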