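#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3D `(z, y, x)` stack to a 2D image by taking the per-pixel
#' maximum across z-sections, the standard reduction applied to foci
#' stacks before 2D analysis.
#'
#' @param stack a 3D numeric array `(z, y, x)`, or a 2D matrix (returned
#'   unchanged), or an `image_stack` object (see [render_image_stack()]),
#'   in which case `channel` selects the channel to project.
#' @param channel channel name, used only when `stack` is an `image_stack`.
#' @return a 2D numeric matrix `(y, x)`.
#' @export
max_project <- function(stack, channel = NULL) {
  if (inherits(stack, "image_stack")) {
    stopifnot(!is.null(channel), channel %in% names(stack$channels))
    stack <- stack$channels[[channel]]
  }
  if (is.matrix(stack)) return(stack)
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("`stack` must be a (z, y, x) array or a matrix")
  if (dim(stack)[1L] < 1L) stop("empty stack: no z-sections")
  apply(stack, c(2L, 3L), max)
}

#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a 2D image
#' @param img numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return smoothed matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  cpp_convolve_sep(img, gaussian_kernel_1d(sigma))
}

#' @keywords internal
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, , drop = FALSE]
  g
}

#' Grayscale morphology with a disk structuring element
#'
#' @param img numeric matrix.
#' @param radius disk radius in pixels.
#' @name morphology
#' @return transformed matrix.
#' @export
im_dilate <- function(img, radius) {
  o <- disk_offsets(radius)
  cpp_gray_morph(img, o$dy, o$dx, TRUE)
}

#' @rdname morphology
#' @export
im_erode <- function(img, radius) {
  o <- disk_offsets(radius)
  cpp_gray_morph(img, o$dy, o$dx, FALSE)
}

#' @rdname morphology
#' @export
im_open <- function(img, radius) im_dilate(im_erode(img, radius), radius)

#' @rdname morphology
#' @export
im_close <- function(img, radius) im_erode(im_dilate(img, radius), radius)

#' White top-hat transform
#'
#' `img - opening(img)`: removes background structure larger than the
#' structuring element, retaining bright spots smaller than the disk.
#'
#' @inheritParams morphology
#' @return matrix of residual (spot) intensities, >= 0.
#' @export
white_tophat <- function(img, radius) {
  out <- img - im_open(img, radius)
  out[out < 0] <- 0
  out
}

#' Otsu threshold of an intensity sample
#'
#' Classic bimodal-histogram threshold maximizing between-class variance,
#' computed on a 256-bin histogram of the supplied intensities.
#'
#' @param x numeric vector (or matrix) of intensities.
#' @param n_bins histogram resolution.
#' @return scalar threshold on the intensity scale.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - rng[1]) / diff(rng) * n_bins)), n_bins)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

#' Fill holes in a binary mask
#'
#' A hole is a background component not connected (4-connectivity) to the
#' image border.
#'
#' @param mask logical matrix.
#' @return logical matrix with interior holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  bg <- cpp_label(!mask, 4L)
  border <- unique(c(bg[1L, ], bg[nrow(bg), ], bg[, 1L], bg[, ncol(bg)]))
  border <- border[border > 0L]
  hole <- bg > 0L & !matrix(bg %in% border, nrow(bg), ncol(bg))
  mask | hole
}

#' Label connected components
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer label matrix (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  cpp_label(mask, as.integer(connectivity))
}

#' Euclidean distance transform
#' @param mask logical matrix; distances are computed for `TRUE` pixels to
#'   the nearest `FALSE` pixel (exact Euclidean metric).
#' @return numeric matrix of distances in pixels.
#' @export
distance_transform <- function(mask) cpp_edt(mask)

#' Marker-directed watershed
#'
#' Priority-flood from labelled seed pixels over a height image,
#' restricted to a mask; used to separate touching nuclei and touching
#' foci.
#'
#' @param height numeric matrix to flood (lower values flood first).
#' @param markers integer matrix of seed labels (0 elsewhere).
#' @param mask logical matrix restricting the flood.
#' @return integer label matrix.
#' @export
watershed <- function(height, markers, mask) {
  cpp_watershed(height, markers, mask)
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, then hysteresis thresholding.
#'
#' @param img numeric matrix.
#' @param sigma smoothing sigma (px).
#' @param low,high hysteresis thresholds on gradient magnitude. If `NULL`
#'   they default to the 70th / 90th percentile of the nonzero magnitudes.
#' @param mask optional logical matrix; percentiles are computed inside it.
#' @return logical edge matrix.
#' @export
canny_edges <- function(img, sigma = 1.5, low = NULL, high = NULL, mask = NULL) {
  sm <- gaussian_blur(img, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  # Sobel gradients via separable convolution on shifted copies
  pad <- function(m, dy, dx) {
    yy <- pmin(pmax(seq_len(nr) + dy, 1L), nr)
    xx <- pmin(pmax(seq_len(nc) + dx, 1L), nc)
    m[yy, xx, drop = FALSE]
  }
  gy <- (pad(sm, 1, -1) + 2 * pad(sm, 1, 0) + pad(sm, 1, 1)) -
        (pad(sm, -1, -1) + 2 * pad(sm, -1, 0) + pad(sm, -1, 1))
  gx <- (pad(sm, -1, 1) + 2 * pad(sm, 0, 1) + pad(sm, 1, 1)) -
        (pad(sm, -1, -1) + 2 * pad(sm, 0, -1) + pad(sm, 1, -1))
  mag <- sqrt(gx^2 + gy^2)
  sel <- if (is.null(mask)) mag > 0 else (mask & mag > 0)
  if (is.null(high)) high <- quantile(mag[sel], 0.90, names = FALSE)
  if (is.null(low)) low <- quantile(mag[sel], 0.70, names = FALSE)
  # non-maximum suppression: compare along quantized gradient direction
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  off <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    d <- off[[s + 1L]]
    a <- pad(mag, d[1L], d[2L])
    b <- pad(mag, -d[1L], -d[2L])
    nms <- nms | (sector == s & mag >= a & mag >= b)
  }
  strong <- nms & mag >= high
  weak <- nms & mag >= low
  if (!is.null(mask)) { strong <- strong & mask; weak <- weak & mask }
  cpp_hysteresis(strong, weak)
}

#' Local maxima of an image
#'
#' @param img numeric matrix.
#' @param mask logical matrix restricting the search.
#' @param min_distance minimum separation between reported maxima (px).
#' @param threshold minimum intensity of a reported maximum.
#' @return data.frame with 1-based `y`, `x` and `value` columns, ordered by
#'   decreasing intensity.
#' @export
local_maxima <- function(img, mask = NULL, min_distance = 2L, threshold = -Inf) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  df <- cpp_local_maxima(img, mask, as.integer(min_distance), threshold)
  df$y <- df$y + 1L
  df$x <- df$x + 1L
  df
}
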