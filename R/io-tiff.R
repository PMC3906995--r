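# Minimal baseline TIFF support (little-endian, uncompressed, 16-bit
# grayscale, multi-page). Covers exactly what the simulator writes and
# the detector reads; no R TIFF library is assumed.

#' Write a z-stack as a multi-page 16-bit TIFF
#'
#' @param stack numeric matrix (one page) or `(z, y, x)` array (one page
#'   per section). Values are rounded and clipped to `[0, 65535]`.
#' @param path output file.
#' @param description ASCII string stored in the ImageDescription tag of
#'   every page (e.g. `"seed=11"`).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path, description = "") {
  if (is.matrix(stack)) stack <- array(stack, dim = c(1L, dim(stack)))
  stopifnot(length(dim(stack)) == 3L)
  nz <- dim(stack)[1L]; nr <- dim(stack)[2L]; nc <- dim(stack)[3L]
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  desc <- c(charToRaw(description), as.raw(0L))
  if (length(desc) %% 2L == 1L) desc <- c(desc, as.raw(0L))
  page_bytes <- nr * nc * 2L
  n_entries <- if (nchar(description)) 8L else 7L
  ifd_bytes <- 2L + n_entries * 12L + 4L
  # layout: header | page data... | desc strings... | IFDs...
  data_off <- 8L
  desc_off <- data_off + nz * page_bytes
  ifd_off <- desc_off + nz * length(desc)
  writeBin(charToRaw("II"), con)
  w2(42L)
  w4(ifd_off)
  for (z in seq_len(nz)) {
    page <- t(stack[z, , ])  # write row-major: transpose (y, x) matrix
    v <- as.integer(pmin(65535, pmax(0, round(as.numeric(page)))))
    writeBin(v, con, size = 2L, endian = "little")
  }
  for (z in seq_len(nz)) writeBin(desc, con)
  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (z in seq_len(nz)) {
    w2(n_entries)
    entry(256L, 3L, 1L, nc)                      # ImageWidth
    entry(257L, 3L, 1L, nr)                      # ImageLength
    entry(258L, 3L, 1L, 16L)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    if (nchar(description))
      entry(270L, 2L, length(desc), desc_off + (z - 1L) * length(desc))
    entry(273L, 4L, 1L, data_off + (z - 1L) * page_bytes)  # StripOffsets
    entry(279L, 4L, 1L, page_bytes)              # StripByteCounts
    next_ifd <- if (z < nz) ifd_off + z * ifd_bytes else 0L
    w4(next_ifd)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports the baseline subset the package writes: little-endian,
#' uncompressed, 8- or 16-bit grayscale, strip-organized.
#'
#' @param path TIFF file.
#' @return a `(z, y, x)` numeric array with attribute `description`
#'   (per-page ImageDescription strings, if present).
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  u2 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u4 <- function(off) sum(as.numeric(raw[off + 1:4]) * 256^(0:3))
  if (rawToChar(raw[1:2]) != "II" || u2(2L) != 42L)
    stop("not a little-endian TIFF")
  ifd <- u4(4L)
  pages <- list(); descs <- character(0)
  while (ifd != 0) {
    n <- u2(ifd)
    tags <- list()
    for (i in seq_len(n)) {
      e <- ifd + 2L + (i - 1L) * 12L
      tag <- u2(e); type <- u2(e + 2L); count <- u4(e + 4L)
      val <- if (type == 3L && count == 1L) u2(e + 8L) else u4(e + 8L)
      tags[[as.character(tag)]] <- list(type = type, count = count, value = val)
    }
    need <- function(t) {
      x <- tags[[as.character(t)]]
      if (is.null(x)) stop(sprintf("missing TIFF tag %d", t))
      x$value
    }
    nc <- need(256L); nr <- need(257L)
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]$value
    if (!is.null(tags[["259"]]) && tags[["259"]]$value != 1L)
      stop("compressed TIFF not supported")
    bytes_per <- bits %/% 8L
    off <- need(273L); nbytes <- need(279L)
    if (!is.null(tags[["273"]]) && tags[["273"]]$count > 1L)
      stop("multi-strip TIFF not supported")
    npx <- nbytes %/% bytes_per
    vals <- if (bytes_per == 2L) {
      idx <- off + seq_len(npx) * 2L
      as.numeric(raw[idx - 1L]) + 256 * as.numeric(raw[idx])
    } else {
      as.numeric(raw[off + seq_len(npx)])
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nr, nc, byrow = TRUE)
    d <- tags[["270"]]
    if (!is.null(d)) {
      dr <- raw[d$value + seq_len(d$count)]
      descs <- c(descs, rawToChar(dr[dr != as.raw(0L)]))
    }
    ifd <- u4(ifd + 2L + n * 12L)
  }
  out <- array(0, dim = c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (z in seq_along(pages)) out[z, , ] <- pages[[z]]
  attr(out, "description") <- descs
  out
}
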