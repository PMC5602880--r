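# Minimal baseline-TIFF I/O for single-plane grayscale rasters.
#
# The imaging side of this package deals exclusively in uncompressed 8- or
# 16-bit grayscale TIFFs (one sample per pixel, one plane). No TIFF package
# ships with the target environment, and the baseline format for this case is
# small enough to read and write directly.

#' Write a grayscale matrix as an uncompressed TIFF
#'
#' Values are rounded and clipped to the range of the chosen bit depth.
#' The matrix is stored row-major (row 1 = top image row), little-endian,
#' single strip.
#'
#' @param img numeric or integer matrix of non-negative gray levels.
#' @param path output file path.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff_gray <- function(img, path, bits = 16L) {
  stopifnot(is.matrix(img), bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  v <- round(t(img))           # row-major pixel order
  v[v < 0] <- 0; v[v > maxv] <- maxv
  storage.mode(v) <- "integer"
  nr <- nrow(img); nc <- ncol(img)
  bytes_px <- bits / 8L
  n_tags <- 9L
  # layout: 8-byte header | pixel data | IFD
  data_off <- 8L
  data_len <- nr * nc * bytes_px
  ifd_off <- data_off + data_len
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  if (bits == 8L) {
    writeBin(as.raw(as.vector(v)), con)
  } else {
    writeBin(as.vector(v), con, size = 2, endian = "little")
  }
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) {  # SHORT: left-justified in the 4-byte value field
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256L, 4L, 1L, nc)          # ImageWidth
  tag(257L, 4L, 1L, nr)          # ImageLength
  tag(258L, 3L, 1L, bits)        # BitsPerSample
  tag(259L, 3L, 1L, 1L)          # Compression = none
  tag(262L, 3L, 1L, 1L)          # Photometric = BlackIsZero
  tag(273L, 4L, 1L, data_off)    # StripOffsets
  tag(277L, 3L, 1L, 1L)          # SamplesPerPixel
  tag(278L, 4L, 1L, nr)          # RowsPerStrip
  tag(279L, 4L, 1L, data_len)    # StripByteCounts
  writeBin(0L, con, size = 4, endian = "little")  # next IFD
  invisible(path)
}

#' Read an uncompressed grayscale TIFF
#'
#' Supports what [write_tiff_gray()] produces plus the common single-sample
#' baseline variants (either byte order, multiple strips, 8 or 16 bit).
#'
#' @param path file path.
#' @return numeric matrix of gray levels.
#' @export
read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  u <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = FALSE)
  }
  u4 <- function(off, n = 1L) {  # unsigned 32-bit without overflow
    b <- as.integer(raw[(off + 1):(off + 4 * n)])
    dim(b) <- c(4L, n)
    if (endian == "big") b <- b[4:1, , drop = FALSE]
    as.vector(b[1, ] + b[2, ] * 256 + b[3, ] * 65536 + b[4, ] * 16777216)
  }
  if (u(2, 2) != 42L) stop("not a TIFF file: ", path)
  ifd <- u4(4)
  n_tags <- u(ifd, 2)
  tags <- list()
  for (t in seq_len(n_tags)) {
    base <- ifd + 2 + (t - 1) * 12
    id <- u(base, 2); type <- u(base + 2, 2); count <- u4(base + 4)
    val_off <- base + 8
    sz <- c(1, 1, 2, 4, 8)[type]
    vals <- if (sz * count <= 4) {
      if (type == 3L) u(val_off, 2, count) else u4(val_off, count)
    } else {
      off <- u4(val_off)
      if (type == 3L) u(off, 2, count) else u4(off, count)
    }
    tags[[as.character(id)]] <- vals
  }
  need <- function(id, default = NULL) {
    v <- tags[[as.character(id)]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing TIFF tag ", id)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8L)[1]
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (need(277, 1L) != 1L) stop("multi-sample TIFF not supported")
  offs <- need(273)
  counts <- need(279, h * w * bits / 8)
  px <- integer(0)
  for (s in seq_along(offs)) {
    n_px <- counts[s] / (bits / 8)
    px <- c(px, u(offs[s], bits / 8, n_px))
  }
  if (length(px) != w * h) stop("pixel count mismatch in ", path)
  matrix(px, nrow = h, ncol = w, byrow = TRUE) * 1.0
}
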