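#' Stochastic decay of an integer break count
#'
#' Each of the `n0` breaks is repaired after an independent exponential
#' lifetime with rate `log(2) / halflife`, so the expected count at time
#' `t` is `n0 * 2^(-t / halflife)` while individual series remain integer
#' and non-increasing — the generative inverse of the exponential decay
#' model fitted by [fit_exponential()].
#'
#' @param n0 integer initial break count at `times[1]`.
#' @param halflife foci half-life, hours (> 0).
#' @param times ascending time grid in hours starting at 0.
#' @return integer vector of break counts, one per time point;
#'   `series[1] == n0` and the series is non-increasing.
#' @examples
#' simulate_break_decay(20, 6, seq(0, 24, by = 2 / 3))
#' @export
simulate_break_decay <- function(n0, halflife, times) {
  if (!is.numeric(halflife) || halflife <= 0)
    stop("`halflife` must be a positive number of hours")
  n0 <- as.integer(n0)
  if (n0 < 0) stop("`n0` must be >= 0")
  if (length(times) < 1L || is.unsorted(times, strictly = TRUE) || times[1L] != 0)
    stop("`times` must be strictly ascending and start at 0")
  if (n0 == 0L) return(integer(length(times)))
  lifetimes <- rexp(n0, rate = log(2) / halflife)
  vapply(times, function(t) sum(lifetimes > t), integer(1L))
}

#' @keywords internal
draw_initial_breaks <- function(n, cfg) {
  if (cfg$n0_distribution == "uniform") {
    sample(seq.int(cfg$n0_range[1L], cfg$n0_range[2L]), n, replace = TRUE)
  } else if (cfg$dose_mean_breaks == 0) {
    integer(n)
  } else if (!is.finite(cfg$break_dispersion)) {
    rpois(n, cfg$dose_mean_breaks)
  } else {
    rnbinom(n, size = cfg$break_dispersion, mu = cfg$dose_mean_breaks)
  }
}

#' @keywords internal
draw_halflife <- function(n, cfg) {
  # log-normal with given median and CV: sdlog^2 = log(1 + CV^2)
  sdlog <- sqrt(log(1 + cfg$halflife_cv^2))
  rlnorm(n, meanlog = log(cfg$halflife_median), sdlog = sdlog)
}

#' @keywords internal
draw_dapi <- function(n, cfg) {
  # bimodal DNA content: 2N mode at 0.25 and 4N mode at 0.5 of the
  # arbitrary-unit scale, plus a small bright doublet/debris tail that
  # anchors the 99.5th-percentile normalization used downstream.
  comp <- runif(n)
  x <- numeric(n)
  g1 <- comp < cfg$g1_fraction * (1 - cfg$doublet_fraction)
  dbl <- comp >= 1 - cfg$doublet_fraction
  sg2 <- !g1 & !dbl
  x[g1] <- rnorm(sum(g1), 0.25, 0.022) * cfg$dapi_scale
  x[sg2] <- rnorm(sum(sg2), 0.50, 0.040) * cfg$dapi_scale
  x[dbl] <- runif(sum(dbl), 0.70, 1.05) * cfg$dapi_scale
  pmax(x, 0)
}
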