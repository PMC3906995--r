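#' Track nuclei across timepoints by greedy nearest-centroid matching
#'
#' Matches each frame's nuclei to the previous frame's live tracks by
#' ascending centroid distance, subject to a maximum-displacement gate.
#' Unmatched nuclei start new ids; a track whose nucleus finds no match
#' within the gate is terminated (never silently swapped). Synthetic
#' nuclei are static, so tracking is exact there.
#'
#' @param masks list of `nucleus_mask` objects (or of per-frame
#'   data.frames with `label`, `cy`, `cx`), one per timepoint, >= 2.
#' @param max_displacement gate in pixels.
#' @return data.frame with `frame`, `label`, `cell_id`; `cell_id` is
#'   stable along a track.
#' @export
track_nuclei <- function(masks, max_displacement = 10) {
  if (length(masks) < 2L) stop("need >= 2 timepoints")
  get_tab <- function(m) if (inherits(m, "nucleus_mask")) m$nuclei else m
  out <- list()
  prev <- get_tab(masks[[1L]])
  prev$cell_id <- seq_len(nrow(prev))
  next_id <- nrow(prev) + 1L
  out[[1L]] <- data.frame(frame = 1L, label = prev$label, cell_id = prev$cell_id)
  for (f in 2L:length(masks)) {
    cur <- get_tab(masks[[f]])
    cur$cell_id <- NA_integer_
    if (nrow(cur) && nrow(prev)) {
      d <- outer(cur$cy, prev$cy, "-")^2 + outer(cur$cx, prev$cx, "-")^2
      pairs <- which(d <= max_displacement^2, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(d[pairs]), , drop = FALSE]
        used_cur <- logical(nrow(cur)); used_prev <- logical(nrow(prev))
        for (k in seq_len(nrow(pairs))) {
          i <- pairs[k, 1L]; j <- pairs[k, 2L]
          if (!used_cur[i] && !used_prev[j]) {
            cur$cell_id[i] <- prev$cell_id[j]
            used_cur[i] <- TRUE; used_prev[j] <- TRUE
          }
        }
      }
    }
    new <- is.na(cur$cell_id)
    if (any(new)) {
      cur$cell_id[new] <- seq.int(next_id, length.out = sum(new))
      next_id <- next_id + sum(new)
    }
    out[[f]] <- data.frame(frame = f, label = cur$label, cell_id = cur$cell_id)
    prev <- cur
  }
  do.call(rbind, out)
}
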