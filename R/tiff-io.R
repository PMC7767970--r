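# Minimal multi-page baseline TIFF I/O (uncompressed, little-endian, one
# sample per pixel). Only what the pipeline's products need: 8/16-bit
# unsigned integer and 32-bit float pages. No R TIFF bindings are assumed.

TIFF_TAGS <- c(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, spp = 277L,
  rows_per_strip = 278L, strip_counts = 279L, sample_format = 339L
)

#' Write a multi-page TIFF
#'
#' Writes a stack of frames as an uncompressed little-endian baseline TIFF,
#' one page per frame, one strip per page.
#'
#' @param data 3-D numeric array (frames x rows x cols) or a single matrix.
#' @param path Output file path.
#' @param bits Bits per sample: 8 or 16 for unsigned integer pages, 32 for
#'   IEEE float pages.
#' @param sample_format `"uint"` or `"float"`. Defaults to `"float"` when
#'   `bits = 32`, `"uint"` otherwise.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(data, path, bits = 16L,
                       sample_format = if (bits == 32L) "float" else "uint") {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  sample_format <- match.arg(sample_format, c("uint", "float"))
  bits <- as.integer(bits)
  if (sample_format == "uint" && !bits %in% c(8L, 16L))
    stop("uint pages must be 8- or 16-bit")
  if (sample_format == "float" && bits != 32L)
    stop("float pages must be 32-bit")
  n <- dim(data)[1L]; h <- dim(data)[2L]; w <- dim(data)[3L]
  bytes_px <- bits %/% 8L
  strip_bytes <- w * h * bytes_px
  if (sample_format == "uint") {
    if (any(!is.finite(data))) stop("non-finite values in integer TIFF data")
    if (any(data < 0) || any(data > 2^bits - 1))
      stop(sprintf("values outside [0, %d] cannot be stored as %d-bit unsigned",
                   2^bits - 1, bits))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2L, eos = NULL)
  writeBin(42L, con, size = 2L, endian = "little")
  data_start <- 8L
  ifd_start <- data_start + n * strip_bytes
  ifd_size <- 2L + 10L * 12L + 4L           # 10 entries per page
  writeBin(ifd_start, con, size = 4L, endian = "little")

  for (i in seq_len(n)) {
    # TIFF strips are row-major
    v <- as.vector(t(data[i, , , drop = TRUE]))
    if (sample_format == "float") {
      writeBin(as.double(v), con, size = 4L, endian = "little")
    } else {
      writeBin(as.integer(round(v)), con, size = bytes_px, endian = "little",
               useBytes = TRUE)
    }
  }

  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2L, endian = "little")
    writeBin(as.integer(type), con, size = 2L, endian = "little")
    writeBin(as.integer(count), con, size = 4L, endian = "little")
    if (type == 3L) {                       # SHORT, left-justified in 4 bytes
      writeBin(as.integer(value), con, size = 2L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4L, endian = "little")
    }
  }
  fmt_code <- if (sample_format == "float") 3L else 1L
  for (i in seq_len(n)) {
    writeBin(10L, con, size = 2L, endian = "little")
    entry(256L, 4L, 1L, w)
    entry(257L, 4L, 1L, h)
    entry(258L, 3L, 1L, bits)
    entry(259L, 3L, 1L, 1L)                 # no compression
    entry(262L, 3L, 1L, 1L)                 # black is zero
    entry(273L, 4L, 1L, data_start + (i - 1L) * strip_bytes)
    entry(277L, 3L, 1L, 1L)
    entry(278L, 4L, 1L, h)
    entry(279L, 4L, 1L, strip_bytes)
    entry(339L, 3L, 1L, fmt_code)
    nxt <- if (i < n) ifd_start + i * ifd_size else 0L
    writeBin(as.integer(nxt), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a multi-page TIFF
#'
#' Reads an uncompressed single-sample-per-pixel TIFF (as written by
#' [write_tiff()] or any writer of baseline grayscale TIFFs) into a numeric
#' array.
#'
#' @param path TIFF file path.
#' @return 3-D numeric array (frames x rows x cols).
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (length(raw_all) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  u16 <- function(off) readBin(raw_all[off + 1:2], "integer", size = 2L,
                               signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw_all[off + 1:4], "integer", size = 4L,
                               endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF file: ", path)

  pages <- list()
  ifd_off <- u32(4L)
  while (ifd_off != 0L) {
    n_entries <- u16(ifd_off)
    tags <- list()
    for (j in seq_len(n_entries)) {
      e <- ifd_off + 2L + (j - 1L) * 12L
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, NA_integer_)
      if (is.na(size)) { tags[[as.character(tag)]] <- NULL; next }
      total <- size * count
      voff <- if (total <= 4L) e + 8L else u32(e + 8L)
      vals <- vapply(seq_len(count), function(k) {
        o <- voff + (k - 1L) * size
        if (size == 2L) u16(o) else if (size == 4L) u32(o)
        else as.integer(raw_all[o + 1L])
      }, integer(1))
      tags[[as.character(tag)]] <- vals
    }
    gettag <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    w <- gettag(256L); h <- gettag(257L)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions")
    bits <- gettag(258L, 1L)[1L]
    if (gettag(259L, 1L)[1L] != 1L) stop("compressed TIFF not supported")
    if (gettag(277L, 1L)[1L] != 1L) stop("only single-sample TIFF supported")
    fmt <- gettag(339L, 1L)[1L]
    offsets <- gettag(273L); counts <- gettag(279L)
    if (is.null(offsets) || is.null(counts)) stop("TIFF page missing strip layout")
    strip_raw <- unlist(lapply(seq_along(offsets), function(k)
      raw_all[offsets[k] + seq_len(counts[k])]), use.names = FALSE)
    npx <- as.integer(w) * as.integer(h)
    v <- if (fmt == 3L) {
      readBin(strip_raw, "double", n = npx, size = 4L, endian = endian)
    } else if (bits == 8L) {
      as.integer(strip_raw[seq_len(npx)])
    } else {
      readBin(strip_raw, "integer", n = npx, size = bits %/% 8L,
              signed = FALSE, endian = endian)
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- u32(ifd_off + 2L + n_entries * 12L)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  dm <- vapply(pages, dim, integer(2))
  if (any(dm[1, ] != dm[1, 1]) || any(dm[2, ] != dm[2, 1]))
    stop("TIFF pages have differing sizes")
  out <- array(0, c(length(pages), dm[1, 1], dm[2, 1]))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}
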