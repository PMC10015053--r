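# Minimal baseline-TIFF codec: uncompressed greyscale 8/16-bit unsigned,
# multi-page, little- or big-endian on read, little-endian on write.
# Scope is deliberately narrow -- this is an interchange format for the
# package's own fixtures and for images exported by Fiji/tifffile with
# default (uncompressed) settings. Anything fancier (LZW, tiles, RGB,
# floats) is rejected with a clear error.

.TAG_WIDTH <- 256L; .TAG_LENGTH <- 257L; .TAG_BPS <- 258L; .TAG_COMP <- 259L
.TAG_PHOTO <- 262L; .TAG_STRIP_OFF <- 273L; .TAG_SPP <- 277L
.TAG_ROWS_PER_STRIP <- 278L; .TAG_STRIP_CNT <- 279L; .TAG_SAMPLE_FMT <- 339L

#' Read a greyscale multi-page TIFF
#'
#' Supports uncompressed (baseline) greyscale images, 8 or 16 bit
#' unsigned, strip layout, either byte order. Pages must share one
#' shape and bit depth.
#'
#' @param path file path.
#' @return numeric array `c(n_pages, height, width)`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("read_tiff: no such file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("read_tiff: not a TIFF (too short)")
  order_tag <- rawToChar(raw[1:2])
  le <- if (order_tag == "II") TRUE else if (order_tag == "MM") FALSE else
    stop("read_tiff: not a TIFF (bad byte-order mark)")
  rd_int <- function(off, size, n = 1L)   # off is 0-based; 4-byte reads are
    readBin(raw[(off + 1L):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L,           # signed (fine below 2 GiB files)
            endian = if (le) "little" else "big")
  magic <- rd_int(2L, 2L)
  if (magic != 42L) stop("read_tiff: bad TIFF magic number")
  ifd_off <- rd_int(4L, 4L)
  pages <- list()
  while (ifd_off != 0L) {
    n_entries <- rd_int(ifd_off, 2L)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd_int(eoff, 2L)
      typ <- rd_int(eoff + 2L, 2L)
      cnt <- rd_int(eoff + 4L, 4L)
      size <- c(1L, 1L, 2L, 4L, 8L)[typ]   # BYTE ASCII SHORT LONG RATIONAL
      if (is.na(size)) { tags[[as.character(tag)]] <- NULL; next }
      vsize <- size * cnt
      voff <- if (vsize <= 4L) eoff + 8L else rd_int(eoff + 8L, 4L)
      val <- if (typ %in% c(3L, 4L)) rd_int(voff, size, cnt) else NA
      tags[[as.character(tag)]] <- val
    }
    g <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) default else v
    }
    w <- g(.TAG_WIDTH); h <- g(.TAG_LENGTH)
    if (is.null(w) || is.null(h)) stop("read_tiff: IFD missing image dimensions")
    bps <- g(.TAG_BPS, 1L)[1L]
    if (!bps %in% c(8L, 16L)) stop("read_tiff: only 8/16-bit greyscale supported, got ", bps)
    if (g(.TAG_COMP, 1L) != 1L) stop("read_tiff: only uncompressed TIFF supported")
    if (g(.TAG_SPP, 1L) != 1L) stop("read_tiff: only 1 sample per pixel supported")
    sf <- g(.TAG_SAMPLE_FMT, 1L)[1L]
    if (sf != 1L) stop("read_tiff: only unsigned-integer samples supported")
    offs <- g(.TAG_STRIP_OFF); cnts <- g(.TAG_STRIP_CNT)
    if (is.null(offs) || is.null(cnts)) stop("read_tiff: missing strip layout")
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1L):(offs[i] + cnts[i])]), use.names = FALSE)
    px <- readBin(as.raw(bytes), "integer", n = w * h, size = bps / 8L,
                  signed = FALSE, endian = if (le) "little" else "big")
    pages[[length(pages) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd_int(ifd_off + 2L + n_entries * 12L, 4L)
  }
  if (length(pages) == 0L) stop("read_tiff: no pages")
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("read_tiff: pages differ in shape")
  arr <- array(0, dim = c(length(pages), dims[1L, 1L], dims[2L, 1L]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Write a greyscale multi-page TIFF
#'
#' @param pixels numeric matrix (one page) or array `c(n_pages, h, w)`;
#'   values must be finite, non-negative integers within the bit depth.
#' @param path output path.
#' @param bits 8 or 16 (unsigned).
#' @export
write_tiff <- function(pixels, path, bits = 16L) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(1L, dim(pixels)))
  stopifnot(length(dim(pixels)) == 3L, bits %in% c(8L, 16L))
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("write_tiff: pixels must be finite and >= 0")
  maxv <- 2^bits - 1
  if (any(pixels > maxv)) stop("write_tiff: pixel value exceeds ", bits, "-bit range")
  np <- dim(pixels)[1L]; h <- dim(pixels)[2L]; w <- dim(pixels)[3L]
  bpp <- bits / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeBin(charToRaw("II"), con); wr(42L, 2L)
  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  data_off <- 8L
  first_ifd <- data_off + h * w * bpp
  wr(first_ifd, 4L)
  entry <- function(tag, typ, cnt, val) { wr(tag, 2L); wr(typ, 2L); wr(cnt, 4L); wr(val, 4L) }
  for (p in seq_len(np)) {
    m <- round(matrix(pixels[p, , ], h, w))
    writeBin(as.integer(as.vector(t(m))), con, size = bpp, endian = "little")
    ifd_off <- data_off + h * w * bpp
    wr(n_tags, 2L)
    entry(.TAG_WIDTH, 4L, 1L, w)
    entry(.TAG_LENGTH, 4L, 1L, h)
    entry(.TAG_BPS, 3L, 1L, bits)
    entry(.TAG_COMP, 3L, 1L, 1L)
    entry(.TAG_PHOTO, 3L, 1L, 1L)       # BlackIsZero
    entry(.TAG_STRIP_OFF, 4L, 1L, data_off)
    entry(.TAG_SPP, 3L, 1L, 1L)
    entry(.TAG_ROWS_PER_STRIP, 4L, 1L, h)
    entry(.TAG_STRIP_CNT, 4L, 1L, h * w * bpp)
    entry(.TAG_SAMPLE_FMT, 3L, 1L, 1L)
    next_off <- if (p < np) ifd_off + ifd_size + h * w * bpp else 0L
    wr(next_off, 4L)
    data_off <- ifd_off + ifd_size
  }
  invisible(path)
}
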