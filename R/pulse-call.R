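#' Normalize a p53 reporter trajectory to its pre-stimulus baseline
#'
#' Divides the raw nuclear intensity by the cell's own baseline — the
#' median of frames strictly before `damage_time`, or of the first three
#' frames when no pre-stimulus frame exists — making pulse prominence
#' comparable across cells with different reporter expression
#' (baseline ~ 1, dimensionless).
#'
#' @param times hours, strictly ascending, >= 10 samples.
#' @param level raw mean nuclear intensity, au, finite and non-negative.
#' @param damage_time hours.
#' @return list with `times`, `normalized` and the `baseline` used.
#' @export
normalize_trajectory <- function(times, level, damage_time = 0) {
  if (length(times) < 10L) stop("need >= 10 samples")
  if (length(times) != length(level)) stop("`times` and `level` lengths differ")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly ascending")
  if (any(!is.finite(level)) || any(level < 0)) stop("`level` must be finite and >= 0")
  pre <- level[times < damage_time]
  baseline <- if (length(pre)) median(pre) else median(level[1:3])
  if (baseline <= 0) stop("zero pre-stimulus baseline; cannot normalize")
  list(times = times, normalized = level / baseline, baseline = baseline)
}

#' @keywords internal
moving_average <- function(x, k = 3L) {
  if (k <= 1L) return(x)
  n <- length(x)
  pad <- c(rep(x[1L], k %/% 2), x, rep(x[n], k %/% 2))
  as.numeric(stats::filter(pad, rep(1 / k, k), sides = 2L))[(k %/% 2 + 1L):(k %/% 2 + n)]
}

#' Call p53 pulses in a normalized trajectory
#'
#' Smooths with a short moving average, finds local maxima whose
#' topographic prominence (height above the higher of the two
#' surrounding troughs, measured between higher peaks) exceeds
#' `min_prominence`, enforces a minimum separation (keeping the higher
#' peak), and records onset/offset where the smoothed signal crosses
#' `edge_frac` of the prominence above the surrounding trough level, so
#' that the reported duration is the pulse's full visible extent.
#' Pulses narrower than `min_width` are discarded. Deterministic given
#' its parameters.
#'
#' @param times hours.
#' @param normalized normalized trajectory (see [normalize_trajectory()]).
#' @param min_prominence minimum prominence (dimensionless; 0.5 = 50%
#'   above baseline).
#' @param min_width minimum pulse duration, hours.
#' @param min_separation minimum peak-to-peak separation, hours.
#' @param edge_frac fraction of prominence at which onset/offset are
#'   recorded.
#' @param smooth_k moving-average window, frames.
#' @param cell_id optional identifier.
#' @return an object of class `pulse_calls`: data.frame `pulses`
#'   (`peak_time`, `onset`, `offset`, `duration`, `amplitude`,
#'   `prominence`), `n_pulses`, and `flag` (`"ok"` or `"too-short"`).
#' @export
call_pulses <- function(times, normalized, min_prominence = 0.5,
                        min_width = 2, min_separation = 3,
                        edge_frac = 0.1, smooth_k = 3L, cell_id = NA) {
  empty <- data.frame(peak_time = numeric(0), onset = numeric(0),
                      offset = numeric(0), duration = numeric(0),
                      amplitude = numeric(0), prominence = numeric(0))
  mk <- function(pulses, flag) structure(
    list(cell_id = cell_id, pulses = pulses, n_pulses = nrow(pulses), flag = flag),
    class = "pulse_calls")
  if (diff(range(times)) < min_width) return(mk(empty, "too-short"))
  s <- moving_average(normalized, smooth_k)
  n <- length(s)
  # strict-or-plateau local maxima (first index of a plateau)
  cand <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1L) s[i - 1L] else -Inf
    r <- if (i < n) s[i + 1L] else -Inf
    s[i] > l && s[i] >= r
  }, logical(1L)))
  if (!length(cand)) return(mk(empty, "ok"))

  # topographic prominence: lowest point to the nearest higher peak/edge
  prom <- trough_l <- trough_r <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    lrange <- if (any(s[seq_len(i - 1L)] > s[i]) && i > 1L)
      (max(which(s[seq_len(i - 1L)] > s[i])) ):(i - 1L) else seq_len(max(i - 1L, 1L))
    rrange <- if (i < n && any(s[(i + 1L):n] > s[i]))
      (i + 1L):(i + min(which(s[(i + 1L):n] > s[i]))) else (min(i + 1L, n)):n
    tl <- min(s[lrange]); tr <- min(s[rrange])
    if (i == 1L) tl <- s[1L]
    if (i == n) tr <- s[n]
    prom[j] <- s[i] - max(tl, tr)
    trough_l[j] <- tl; trough_r[j] <- tr
  }
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  trough_l <- trough_l[keep]; trough_r <- trough_r[keep]
  if (!length(cand)) return(mk(empty, "ok"))

  # enforce min_separation, keeping the more prominent peak
  ord <- order(-prom)
  sel <- logical(length(cand))
  for (j in ord) {
    if (!any(sel & abs(times[cand] - times[cand[j]]) < min_separation))
      sel[j] <- TRUE
  }
  cand <- cand[sel]; prom <- prom[sel]
  trough_l <- trough_l[sel]; trough_r <- trough_r[sel]
  o <- order(cand)
  cand <- cand[o]; prom <- prom[o]; trough_l <- trough_l[o]; trough_r <- trough_r[o]

  cross <- function(i, base, level, dir) {
    # walk from peak i in direction dir until the raw trajectory drops
    # below `level`, linearly interpolating the crossing time (raw, not
    # smoothed, so the moving average does not widen the pulse)
    j <- i
    repeat {
      nxt <- j + dir
      if (nxt < 1L || nxt > n) return(times[j])
      if (normalized[nxt] < level) {
        f <- (normalized[j] - level) / (normalized[j] - normalized[nxt])
        f <- min(max(f, 0), 1)
        return(times[j] + f * (times[nxt] - times[j]))
      }
      j <- nxt
    }
  }
  rows <- lapply(seq_along(cand), function(j) {
    i <- cand[j]
    lvl_l <- trough_l[j] + edge_frac * (s[i] - trough_l[j])
    lvl_r <- trough_r[j] + edge_frac * (s[i] - trough_r[j])
    onset <- cross(i, trough_l[j], lvl_l, -1L)
    offset <- cross(i, trough_r[j], lvl_r, +1L)
    data.frame(peak_time = times[i], onset = onset, offset = offset,
               duration = offset - onset, amplitude = normalized[i],
               prominence = prom[j])
  })
  pulses <- do.call(rbind, rows)
  pulses <- pulses[pulses$duration >= min_width, , drop = FALSE]
  # pulses must not overlap: clip shared boundaries at the midpoint
  if (nrow(pulses) > 1L) {
    for (j in seq_len(nrow(pulses) - 1L)) {
      if (pulses$offset[j] > pulses$onset[j + 1L]) {
        mid <- (pulses$peak_time[j] + pulses$peak_time[j + 1L]) / 2
        pulses$offset[j] <- min(pulses$offset[j], mid)
        pulses$onset[j + 1L] <- max(pulses$onset[j + 1L], mid)
      }
    }
    pulses$duration <- pulses$offset - pulses$onset
  }
  rownames(pulses) <- NULL
  mk(pulses, "ok")
}

#' @export
print.pulse_calls <- function(x, ...) {
  cat(sprintf("<pulse_calls> %d pulse(s)%s\n", x$n_pulses,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  if (x$n_pulses > 0) print(x$pulses, digits = 3)
  invisible(x)
}

#' Residual damage after the first pulse and presence of a follow-up pulse
#'
#' For the first detected pulse, reports the break count at the frame
#' nearest the pulse offset and whether any later pulse starts within
#' `window` hours of that offset — the per-cell quantities behind the
#' residual-damage versus subsequent-pulse comparison.
#'
#' @param pulses a `pulse_calls` object with >= 1 pulse.
#' @param times frame times, hours.
#' @param foci_series break counts aligned to `times`.
#' @param window hours after the first pulse's offset in which a
#'   subsequent onset counts.
#' @return list with `breaks_after_pulse` (integer) and `has_subsequent`
#'   (logical).
#' @export
subsequent_pulse_analysis <- function(pulses, times, foci_series, window = 8) {
  stopifnot(inherits(pulses, "pulse_calls"))
  if (pulses$n_pulses < 1L)
    stop("no detected pulses; cell excluded from the subsequent-pulse analysis")
  stopifnot(length(times) == length(foci_series))
  off <- pulses$pulses$offset[1L]
  frame <- which.min(abs(times - off))
  later <- pulses$pulses$onset[-1L]
  list(breaks_after_pulse = as.integer(foci_series[frame]),
       has_subsequent = any(later > off & later <= off + window))
}
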