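#' Binned pulse fraction versus break number
#'
#' Bins cells by break count into half-open bins `[0, W), [W, 2W), ...`
#' and reports the fraction pulsing and the cell count per bin. Empty
#' bins are reported with `n = 0` and `NA` fraction. Bin counts sum to
#' the cohort size.
#'
#' @param x per-cell break counts (>= 0).
#' @param y per-cell logical pulsed flags.
#' @param bin_width bin width in foci (default 4).
#' @return data.frame with `bin_lo`, `bin_hi`, `bin_mid`, `n`, `fraction`.
#' @export
binned_fraction <- function(x, y, bin_width = 4) {
  stopifnot(length(x) == length(y), bin_width > 0)
  if (any(x < 0)) stop("break counts must be non-negative")
  y <- as.logical(y)
  idx <- floor(x / bin_width)
  n_bins <- max(idx) + 1L
  out <- data.frame(bin_lo = (seq_len(n_bins) - 1L) * bin_width)
  out$bin_hi <- out$bin_lo + bin_width
  out$bin_mid <- out$bin_lo + bin_width / 2
  out$n <- vapply(seq_len(n_bins) - 1L, function(b) sum(idx == b), integer(1))
  out$fraction <- vapply(seq_len(n_bins) - 1L, function(b) {
    s <- idx == b
    if (!any(s)) NA_real_ else mean(y[s])
  }, numeric(1))
  out
}

#' @keywords internal
bisquare_weights <- function(r, c = 4.685) {
  w <- (1 - (r / c)^2)^2
  w[abs(r) > c] <- 0
  w
}

#' Robust linear fit of binary outcomes on break counts
#'
#' Linear probability model fitted on per-cell data (not bin means) by
#' iteratively reweighted least squares with Tukey's redescending
#' bisquare weight function and MAD residual scale, plus a pointwise
#' confidence band at level `alpha` from the asymptotic covariance
#' (MASS::rlm-style correction). Predicted probabilities on the fitted
#' line are clipped to `[0, 1]`.
#'
#' @param x per-cell break counts (>= 20 cells, not all equal).
#' @param y per-cell binary pulsed outcomes.
#' @param alpha confidence level complement (default 0.05).
#' @param c_tune bisquare tuning constant, in robust-scale units. The
#'   default 16 keeps every residual a clean binary outcome can produce
#'   (|r| <= 1, about 3.5 robust scales) in the near-unit-weight region,
#'   so the estimator stays consistent for the linear probability while
#'   still rejecting gross (corrupted) residuals; the classical 4.685
#'   would treat legitimate minority responses as outliers and bias the
#'   fit.
#' @param max_iter,tol IRLS controls.
#' @return object of class `robust_fit`: `slope`, `intercept`,
#'   `se_slope`, `se_intercept`, `cov`, `alpha`, and a `band` data.frame
#'   (`x`, `fit`, `lower`, `upper`) over the observed x-range.
#' @export
robust_linear_fit <- function(x, y, alpha = 0.05, c_tune = 16,
                              max_iter = 50L, tol = 1e-8) {
  y <- as.numeric(y)
  if (length(x) < 20L) stop("need >= 20 cells")
  if (length(unique(x)) < 2L) stop("degenerate x: all values equal")
  X <- cbind(1, x)
  beta <- qr.solve(X, y)  # OLS start
  for (it in seq_len(max_iter)) {
    r <- y - X %*% beta
    s <- mad(r, center = 0)
    if (s < 1e-12) break
    w <- bisquare_weights(as.numeric(r) / s, c = c_tune)
    if (sum(w > 0) < 3L) break
    Xw <- X * w
    beta_new <- solve(crossprod(Xw, X), crossprod(Xw, y))
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta <- as.numeric(beta)
  r <- as.numeric(y - X %*% beta)
  s <- mad(r, center = 0)
  n <- length(y); p <- 2L
  if (s < 1e-12) {
    covb <- matrix(0, 2, 2)
  } else {
    u <- r / s
    c_tuk <- c_tune
    psi <- ifelse(abs(u) <= c_tuk, u * (1 - (u / c_tuk)^2)^2, 0)
    psip <- ifelse(abs(u) <= c_tuk,
                   (1 - (u / c_tuk)^2) * (1 - 5 * (u / c_tuk)^2), 0)
    m_psip <- mean(psip)
    kappa <- 1 + p / n * stats::var(psip) / m_psip^2  # Huber correction
    s2 <- s^2 * sum(psi^2) / (n - p) / m_psip^2 * kappa^2
    covb <- s2 * solve(crossprod(X))
  }
  z <- qnorm(1 - alpha / 2)
  xg <- seq(min(x), max(x), length.out = 101L)
  fit <- beta[1L] + beta[2L] * xg
  se_fit <- sqrt(covb[1, 1] + 2 * xg * covb[1, 2] + xg^2 * covb[2, 2])
  band <- data.frame(x = xg, fit = clamp01(fit),
                     lower = clamp01(fit - z * se_fit),
                     upper = clamp01(fit + z * se_fit))
  structure(list(slope = beta[2L], intercept = beta[1L],
                 se_slope = sqrt(covb[2, 2]), se_intercept = sqrt(covb[1, 1]),
                 cov = covb, alpha = alpha, band = band, n = n,
                 c_tune = c_tune,
                 weight_function = sprintf("Tukey bisquare (IRLS, MAD scale, c = %g)", c_tune)),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> p(N) = %.4f + %.4f N  (se %.4f / %.4f, n = %d)\n",
              x$intercept, x$slope, x$se_intercept, x$se_slope, x$n))
  cat(sprintf("  %s; %.0f%% confidence band over [%.1f, %.1f]\n",
              x$weight_function, 100 * (1 - x$alpha),
              min(x$band$x), max(x$band$x)))
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U test. For small samples (both `n <= 8`) the
#' p-value is computed by exact enumeration of all rank assignments of
#' the observed (possibly tied) data; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `statistic` (U of sample `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  n1 <- length(a); n2 <- length(b)
  rk <- rank(c(a, b))
  u_of <- function(idx1) sum(rk[idx1]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  if (n1 <= 8L && n2 <= 8L) {
    combs <- combn(n1 + n2, n1)
    us <- apply(combs, 2L, function(ix) sum(rk[ix])) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p_value = p, method = "exact enumeration"))
  }
  list(statistic = u_obs, p_value = rank_sum_large(a, b),
       method = "normal approximation with tie correction")
}

#' @keywords internal
rank_sum_large <- function(a, b) {
  # tie-corrected normal approximation with continuity correction
  n1 <- length(a); n2 <- length(b); nt <- n1 + n2
  rk <- rank(c(a, b))
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum ECDF gap with the asymptotic p-value.
#'
#' @param a,b numeric samples (nonempty).
#' @return list with `D`, `p_value`.
#' @export
ks_test <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  pts <- sort(unique(c(a, b)))
  fa <- vapply(pts, function(t) mean(a <= t), numeric(1))
  fb <- vapply(pts, function(t) mean(b <= t), numeric(1))
  d <- max(abs(fa - fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lam <- sqrt(ne) * d
  p <- if (lam < 0.2) 1 else {
    k <- 1:100
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lam^2))
  }
  list(D = d, p_value = max(0, min(1, p)))
}

#' Proportion with its standard error
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (> 0).
#' @return list with `fraction` and `se = sqrt(p (1 - p) / n)`.
#' @export
proportion_with_se <- function(k, n) {
  if (length(n) != 1L || n <= 0) stop("`n` must be a single positive count")
  if (k < 0 || k > n) stop("`k` must lie in [0, n]")
  p <- k / n
  if (p == 0 || p == 1)
    warning("degenerate proportion: standard error is 0")
  list(fraction = p, se = sqrt(p * (1 - p) / n))
}

#' Conditional pulse response to repeated damage
#'
#' Stratified proportions for a re-damage design: the overall pulse I
#' and pulse II fractions and the conditional fractions
#' P(pulse II | pulse I) and P(pulse II | no pulse I), each with the
#' standard error of the proportion. When single-stimulus flags are
#' supplied, the single- versus double-stimulus pulse II comparison
#' table is included.
#'
#' @param first_pulsed,second_pulsed equal-length logical vectors for the
#'   double-stimulus cohort (>= 10 cells per conditioning group
#'   recommended; an empty stratum is reported as `NA` with a warning).
#' @param single_second_pulsed optional logical vector: pulse II flags of
#'   a single-stimulus cohort.
#' @return list with `overall` (data.frame of pulse I / pulse II
#'   fractions), `conditional` (data.frame of the two conditional
#'   fractions), and optionally `stimulus_comparison`.
#' @export
repeated_damage_analysis <- function(first_pulsed, second_pulsed,
                                     single_second_pulsed = NULL) {
  stopifnot(length(first_pulsed) == length(second_pulsed))
  first_pulsed <- as.logical(first_pulsed)
  second_pulsed <- as.logical(second_pulsed)
  prop_row <- function(label, flags) {
    if (!length(flags)) {
      warning(sprintf("empty stratum '%s': reported as NA", label))
      return(data.frame(group = label, n = 0L, fraction = NA_real_, se = NA_real_))
    }
    ps <- suppressWarnings(proportion_with_se(sum(flags), length(flags)))
    data.frame(group = label, n = length(flags), fraction = ps$fraction, se = ps$se)
  }
  overall <- rbind(prop_row("pulse I", first_pulsed),
                   prop_row("pulse II", second_pulsed))
  conditional <- rbind(
    prop_row("pulse II | pulse I", second_pulsed[first_pulsed]),
    prop_row("pulse II | no pulse I", second_pulsed[!first_pulsed]))
  grp_n <- c(sum(first_pulsed), sum(!first_pulsed))
  if (any(grp_n > 0L & grp_n < 10L))
    warning("a conditioning group has fewer than 10 cells")
  out <- list(overall = overall, conditional = conditional)
  if (!is.null(single_second_pulsed)) {
    out$stimulus_comparison <- rbind(
      prop_row("pulse II (single stimulus)", as.logical(single_second_pulsed)),
      prop_row("pulse II (double stimulus)", second_pulsed))
  }
  out
}

#' Classify cell-cycle phase from integrated DNA-stain intensity
#'
#' Normalizes each cell's integrated DAPI/Hoechst intensity by the
#' population's 99.5th percentile (clipped to `[0, 1]`) and assigns G1
#' to cells below 0.33 normalized units and S/G2 to cells at or above it
#' (the boundary is S/G2).
#'
#' @param integrated_dapi per-cell integrated intensities (>= 50 cells).
#' @param cut G1 / S-G2 boundary in normalized units.
#' @return data.frame with `cell_id`, `normalized_dapi`, `phase`
#'   (factor G1 / S/G2).
#' @export
classify_cell_cycle <- function(integrated_dapi, cut = 0.33) {
  if (length(integrated_dapi) < 50L)
    stop("DNA-content normalization needs >= 50 cells")
  ref <- quantile(integrated_dapi, 0.995, names = FALSE)
  if (ref <= 0) stop("non-positive normalization reference")
  norm <- pmin(1, pmax(0, integrated_dapi / ref))
  if (quantile(norm, 0.75) - quantile(norm, 0.25) < 0.1 * median(norm))
    warning("DNA-content distribution looks unimodal; phase calls unreliable")
  data.frame(cell_id = seq_along(integrated_dapi),
             normalized_dapi = norm,
             phase = factor(ifelse(norm < cut, "G1", "S/G2"),
                            levels = c("G1", "S/G2")))
}
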