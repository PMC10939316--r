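# Minimal multi-page TIFF I/O (little-endian, uncompressed, single-sample
# grayscale). Covers what this package writes -- 32-bit float or 8/16-bit
# unsigned integer pages -- and reads the same subset back bit-exactly.
# No pre-installed R package provides TIFF access, hence this small
# self-contained implementation of the classic (non-Big) TIFF layout.

.tiff_tag_ids <- c(ImageWidth = 256L, ImageLength = 257L,
                   BitsPerSample = 258L, Compression = 259L,
                   Photometric = 262L, StripOffsets = 273L,
                   SamplesPerPixel = 277L, RowsPerStrip = 278L,
                   StripByteCounts = 279L, SampleFormat = 339L)

#' Write a multi-page TIFF
#'
#' Writes a `(t, y, x)` numeric array as an uncompressed little-endian
#' grayscale multi-page TIFF, one page per frame.
#'
#' @param arr 3D numeric array `(t, y, x)` (a matrix is treated as one
#'   page).
#' @param path Output file path.
#' @param format `"float32"` (default; lossless for typical image data),
#'   `"uint16"` or `"uint8"` (values are clamped and rounded).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(arr, path, format = c("float32", "uint16", "uint8")) {
  format <- match.arg(format)
  if (is.matrix(arr)) arr <- array(arr, c(1L, nrow(arr), ncol(arr)))
  stopifnot(length(dim(arr)) == 3L)
  n <- dim(arr)[1L]; H <- dim(arr)[2L]; W <- dim(arr)[3L]
  bits <- switch(format, float32 = 32L, uint16 = 16L, uint8 = 8L)
  fmtcode <- if (format == "float32") 3L else 1L
  bytes_pp <- bits %/% 8L
  strip_len <- H * W * bytes_pp

  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  # layout per page: [pixel data][IFD]; first IFD offset points past page 1
  hdr <- 8L
  page_bytes <- strip_len + 2L + 10L * 12L + 4L   # data + IFD block
  ifd_offset <- function(p) hdr + (p - 1L) * page_bytes + strip_len
  data_offset <- function(p) hdr + (p - 1L) * page_bytes
  w32(ifd_offset(1L))
  for (p in seq_len(n)) {
    px <- as.vector(t(arr[p, , ]))          # row-major
    if (format == "float32") {
      writeBin(as.numeric(px), con, size = 4, endian = "little")
    } else {
      mx <- 2^bits - 1
      v <- as.integer(pmin(pmax(round(px), 0), mx))
      writeBin(v, con, size = bytes_pp, endian = "little")
    }
    w16(10L)                                 # tag count
    tag <- function(id, type, count, value) {
      w16(id); w16(type); w32(count)
      if (type == 3L) { w16(value); w16(0L) } else w32(value)
    }
    tag(256L, 3L, 1L, W)
    tag(257L, 3L, 1L, H)
    tag(258L, 3L, 1L, bits)
    tag(259L, 3L, 1L, 1L)                    # uncompressed
    tag(262L, 3L, 1L, 1L)                    # BlackIsZero
    tag(273L, 4L, 1L, data_offset(p))
    tag(277L, 3L, 1L, 1L)
    tag(278L, 3L, 1L, H)
    tag(279L, 4L, 1L, strip_len)
    tag(339L, 3L, 1L, fmtcode)
    w32(if (p < n) ifd_offset(p + 1L) else 0L)
  }
  invisible(path)
}

#' Read a multi-page TIFF
#'
#' Reads uncompressed little-endian single-sample grayscale TIFF files
#' (8/16-bit unsigned integer or 32-bit float) as written by
#' [write_tiff()].
#'
#' @param path File path.
#' @return A 3D numeric array `(t, y, x)`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.numeric(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF file: ", path, call. = FALSE)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    ntag <- u16(ifd)
    tags <- list()
    for (i in seq_len(ntag)) {
      off <- ifd + 2 + (i - 1) * 12
      id <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val <- if (type == 3L) u16(off + 8) else u32(off + 8)
      # out-of-line values (multi-strip offsets/counts)
      if (count > 1L && id %in% c(273L, 279L)) {
        ptr <- u32(off + 8)
        sz <- if (type == 3L) 2 else 4
        val <- vapply(seq_len(count) - 1, function(k)
          if (type == 3L) u16(ptr + k * sz) else u32(ptr + k * sz), 0)
      }
      tags[[as.character(id)]] <- val
    }
    pages[[length(pages) + 1L]] <- tags
    ifd <- u32(ifd + 2 + ntag * 12)
  }
  g <- function(tags, id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) default else v
  }
  n <- length(pages)
  W <- g(pages[[1L]], 256L); H <- g(pages[[1L]], 257L)
  arr <- array(0, c(n, H, W))
  for (p in seq_len(n)) {
    tg <- pages[[p]]
    if (g(tg, 259L, 1L) != 1L)
      stop("compressed TIFF not supported", call. = FALSE)
    if (g(tg, 277L, 1L) != 1L)
      stop("only single-sample grayscale TIFF supported", call. = FALSE)
    bits <- g(tg, 258L, 1L)
    fmt <- g(tg, 339L, 1L)
    offs <- g(tg, 273L); cnts <- g(tg, 279L)
    buf <- raw(0)
    for (s in seq_along(offs))
      buf <- c(buf, raw[(offs[s] + 1):(offs[s] + cnts[s])])
    px <- if (fmt == 3L && bits == 32L) {
      readBin(buf, "double", n = H * W, size = 4, endian = "little")
    } else if (fmt %in% c(1L, 4L) && bits %in% c(8L, 16L)) {
      readBin(buf, "integer", n = H * W, size = bits %/% 8L, signed = FALSE,
              endian = "little")
    } else {
      stop("unsupported TIFF sample format (bits = ", bits,
           ", format = ", fmt, ")", call. = FALSE)
    }
    arr[p, , ] <- matrix(px, H, W, byrow = TRUE)
  }
  arr
}
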