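#' Fit an exponential repair model to one cell's foci series
#'
#' Least-squares fit of `N(t) = N0 * 2^(-t / h)` by nonlinear
#' minimization, parameterized directly by the half-life `h` (hours).
#' Initial values come from the first count and the log-linear slope
#' over positive counts; zero counts are retained in the nonlinear fit
#' (late-time zeros carry information about complete repair).
#'
#' @param times hours, ascending, >= 4 points.
#' @param counts non-negative foci counts aligned to `times`.
#' @param cell_id optional identifier carried into the result.
#' @return an object of class `repair_fit`: `n0_hat`, `halflife_hat`
#'   (hours, `NA` when not usable), `goodness` (1 - SS_res/SS_tot,
#'   clipped to `[0, 1]`), `usable`, and a `flag` (`"ok"`, `"all-zero"`,
#'   `"no-decay"`, `"no-converge"`).
#' @examples
#' t <- seq(0, 24, by = 2 / 3)
#' fit_exponential(t, round(20 * 2^(-t / 6)))
#' @export
fit_exponential <- function(times, counts, cell_id = NA) {
  if (length(times) < 4L) stop("need >= 4 timepoints")
  if (length(times) != length(counts)) stop("`times` and `counts` lengths differ")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("`times` must be strictly ascending")
  times <- times - times[1L]

  res <- function(n0_hat, h_hat, goodness, usable, flag)
    structure(list(cell_id = cell_id, n0_hat = n0_hat, halflife_hat = h_hat,
                   goodness = goodness, usable = usable, flag = flag),
              class = "repair_fit")
  if (all(counts == 0))
    return(res(0, NA_real_, 1, FALSE, "all-zero"))

  # initialization: log-linear regression over positive counts
  pos <- counts > 0
  n0_init <- max(counts[1L], 0.5)
  h_init <- if (sum(pos) >= 2L) {
    sl <- coef(lm(log2(counts[pos]) ~ times[pos]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else NA_real_
  } else NA_real_
  h_max <- 100 * max(times[-1L])
  if (!is.finite(h_init) || h_init <= 0) h_init <- max(times) # weak default
  h_init <- min(h_init, h_max)

  ss <- function(par) {
    n0 <- exp(par[1L]); h <- exp(par[2L])
    sum((counts - n0 * 2^(-times / h))^2)
  }
  opt <- tryCatch(
    optim(c(log(n0_init), log(h_init)), ss, method = "L-BFGS-B",
          lower = c(log(1e-8), log(1e-3)), upper = c(log(1e6), log(h_max)),
          control = list(maxit = 500L)),
    error = function(e) NULL)
  if (is.null(opt))
    return(res(NA_real_, NA_real_, 0, FALSE, "no-converge"))
  n0_hat <- exp(opt$par[1L])
  h_hat <- exp(opt$par[2L])
  ss_tot <- sum((counts - mean(counts))^2)
  goodness <- if (ss_tot > 0) max(0, min(1, 1 - opt$value / ss_tot)) else 1
  if (h_hat >= 0.99 * h_max || ss_tot == 0)
    return(res(n0_hat, NA_real_, goodness, FALSE, "no-decay"))
  res(n0_hat, h_hat, goodness, TRUE, "ok")
}

#' @export
print.repair_fit <- function(x, ...) {
  if (x$usable)
    cat(sprintf("<repair_fit> N0 = %.2f, half-life = %.2f h (goodness %.3f)\n",
                x$n0_hat, x$halflife_hat, x$goodness))
  else
    cat(sprintf("<repair_fit> not usable (%s)\n", x$flag))
  invisible(x)
}

#' Fit repair kinetics for every cell of a records table
#'
#' @param records long data.frame with `cell_id`, `time_h` and a count
#'   column.
#' @param count_col name of the count column (default `"foci_true"`;
#'   use `"foci_count"` for detected counts).
#' @param from_time fit only frames at or after this time (hours),
#'   typically the damage time.
#' @return data.frame with one row per cell: `cell_id`, `n0_hat`,
#'   `halflife_hat`, `goodness`, `usable`, `flag`.
#' @export
fit_repair <- function(records, count_col = "foci_true", from_time = 0) {
  stopifnot(all(c("cell_id", "time_h", count_col) %in% names(records)))
  records <- records[records$time_h >= from_time, , drop = FALSE]
  ids <- unique(records$cell_id)
  rows <- lapply(ids, function(id) {
    r <- records[records$cell_id == id, , drop = FALSE]
    r <- r[order(r$time_h), , drop = FALSE]
    f <- fit_exponential(r$time_h, r[[count_col]], cell_id = id)
    data.frame(cell_id = id, n0_hat = f$n0_hat, halflife_hat = f$halflife_hat,
               goodness = f$goodness, usable = f$usable, flag = f$flag)
  })
  do.call(rbind, rows)
}

#' Population repair summary: median curve and interquartile band
#'
#' @param records long data.frame with `cell_id`, `time_h`, a count
#'   column, and a condition label column.
#' @param condition_col name of the condition column; if absent a single
#'   condition `"all"` is assumed.
#' @param count_col name of the count column.
#' @return data.frame with `condition`, `time_h`, `median`, `q25`, `q75`,
#'   `n_cells` per frame.
#' @export
summarize_repair <- function(records, condition_col = NULL,
                             count_col = "foci_true") {
  if (is.null(condition_col)) {
    records$.cond <- "all"
  } else {
    records$.cond <- records[[condition_col]]
  }
  grids <- tapply(records$time_h, records$cell_id,
                  function(t) paste(sort(unique(t)), collapse = ","))
  if (length(unique(grids)) > 1L)
    stop("cells are on mismatched time grids")
  out <- list()
  for (cond in unique(records$.cond)) {
    r <- records[records$.cond == cond, , drop = FALSE]
    if (length(unique(r$cell_id)) < 3L)
      stop("need >= 3 cells per condition")
    for (t in sort(unique(r$time_h))) {
      v <- r[[count_col]][r$time_h == t]
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, time_h = t, median = median(v),
        q25 = quantile(v, 0.25, names = FALSE),
        q75 = quantile(v, 0.75, names = FALSE), n_cells = length(v))
    }
  }
  do.call(rbind, out)
}
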