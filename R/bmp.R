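# Minimal 24-bit uncompressed BMP codec. ROI masks travel as BMP files
# painted in an ordinary image editor; only the uncompressed 24-bpp dialect
# those editors write is supported. Rows are stored bottom-up (top-down, i.e.
# negative height, is accepted on read) and padded to 4-byte boundaries.

#' Read a 24-bit uncompressed BMP mask image
#'
#' Returns per-pixel RGB triples as an integer array with row 1 at the top of
#' the image, matching the orientation of the temperature frames.
#'
#' @param path path to a BMP file.
#' @return integer array `rows x cols x 3` (R, G, B planes), values 0-255.
#' @export
read_mask_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM") {
    stop(sprintf("not a BMP file: %s", path))
  }
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  s32 <- function(off) { v <- u32(off); if (v >= 2^31) v - 2^32 else v }
  data_off <- u32(10L)
  width <- s32(18L)
  height <- s32(22L)
  bpp <- u16(28L)
  compression <- u32(30L)
  if (bpp != 24L) stop(sprintf("unsupported BMP bit depth %d (need 24): %s", bpp, path))
  if (compression != 0L) stop(sprintf("compressed BMP not supported: %s", path))
  topdown <- height < 0
  height <- abs(height)
  row_bytes <- ((width * 3 + 3) %/% 4) * 4
  need <- data_off + row_bytes * height
  if (length(raw) < need) stop(sprintf("truncated BMP pixel data: %s", path))
  px <- array(0L, dim = c(height, width, 3L))
  for (r in seq_len(height)) {
    # BMP stores rows bottom-up unless height was negative
    img_row <- if (topdown) r else height - r + 1L
    off <- data_off + (r - 1L) * row_bytes
    row <- as.integer(raw[off + seq_len(width * 3)])
    # pixel order within a row is B, G, R
    px[img_row, , 1L] <- row[seq(3L, by = 3L, length.out = width)]
    px[img_row, , 2L] <- row[seq(2L, by = 3L, length.out = width)]
    px[img_row, , 3L] <- row[seq(1L, by = 3L, length.out = width)]
  }
  px
}

#' Write a 24-bit uncompressed BMP image
#'
#' Counterpart of [read_mask_bmp()]; used by the synthetic-cohort generator
#' to emit mask files. Round-trips bit-exactly.
#'
#' @param rgb integer array `rows x cols x 3` with values in 0-255, or a
#'   single-channel 0-255 matrix (replicated to gray RGB).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_bmp <- function(rgb, path) {
  if (is.matrix(rgb)) rgb <- array(rep(rgb, 3L), dim = c(dim(rgb), 3L))
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  if (any(rgb < 0 | rgb > 255)) stop("RGB values must be in [0, 255]")
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  data_size <- row_bytes * h
  file_size <- 54L + data_size
  le <- function(v, n) as.raw((v %/% 256^(0:(n - 1))) %% 256)
  header <- c(
    charToRaw("BM"), le(file_size, 4), le(0, 4), le(54, 4),   # file header
    le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(24, 2),       # info header
    le(0, 4), le(data_size, 4), le(2835, 4), le(2835, 4), le(0, 4), le(0, 4)
  )
  px <- raw(data_size)
  rgb <- round(rgb)
  for (r in seq_len(h)) {
    img_row <- h - r + 1L  # bottom-up
    off <- (r - 1L) * row_bytes
    row <- integer(w * 3)
    row[seq(1L, by = 3L, length.out = w)] <- rgb[img_row, , 3L]
    row[seq(2L, by = 3L, length.out = w)] <- rgb[img_row, , 2L]
    row[seq(3L, by = 3L, length.out = w)] <- rgb[img_row, , 1L]
    px[off + seq_len(w * 3)] <- as.raw(row)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, px), con)
  invisible(path)
}
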