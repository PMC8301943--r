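# Painted RGB mask image -> binary 0/1 ROI matrix. The rule is purely
# pixelwise: luminance conversion, then only pure white (grayscale 255)
# counts as ROI. No morphological cleanup.

#' Convert an RGB image to 8-bit grayscale luminance
#'
#' Per pixel `0.299 R + 0.587 G + 0.114 B`, rounded half-away-from-zero to
#' the nearest integer and clamped to 0-255. The coefficients sum to 1, so
#' neutral gray `(v, v, v)` maps back to `v` exactly.
#'
#' @param rgb integer array `rows x cols x 3` with channel values in 0-255.
#' @return integer matrix of grayscale values 0-255.
#' @export
rgb_to_gray <- function(rgb) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3L] == 3L)
  if (any(rgb < 0 | rgb > 255)) stop("RGB channel value out of range [0, 255]")
  g <- 0.299 * rgb[, , 1L, drop = FALSE] + 0.587 * rgb[, , 2L, drop = FALSE] +
    0.114 * rgb[, , 3L, drop = FALSE]
  g <- matrix(floor(g + 0.5), nrow = dim(rgb)[1L])  # values are non-negative here
  g[g > 255] <- 255
  storage.mode(g) <- "integer"
  g
}

#' Binarize a grayscale mask image
#'
#' Keeps only pixels whose grayscale value is exactly 255 (the painted ROI);
#' everything else -- background, shadows, anti-aliased edges -- becomes 0.
#'
#' @param gray integer matrix of grayscale values 0-255.
#' @param region anatomical region label (`"THIGH"`, `"CALF"`, `"FOOT"`).
#' @param subject_id opaque subject identifier.
#' @return a [binary_mask()].
#' @export
binarize_mask <- function(gray, region, subject_id = NA_character_) {
  if (any(gray < 0 | gray > 255)) stop("grayscale value out of range [0, 255]")
  m <- (gray == 255L) * 1L
  if (sum(m) < 1L) {
    stop(sprintf("empty ROI for region %s of subject %s: no pixel has grayscale 255",
                 region, subject_id))
  }
  binary_mask(m, region = region, subject_id = subject_id)
}

#' Build a binary ROI mask from a painted BMP file
#'
#' Composition `read_mask_bmp` -> `rgb_to_gray` -> `binarize_mask`.
#'
#' @inheritParams binarize_mask
#' @param path path to a 24-bit uncompressed BMP with the ROI painted pure white.
#' @return a [binary_mask()].
#' @export
mask_from_bmp <- function(path, region, subject_id = NA_character_) {
  binarize_mask(rgb_to_gray(read_mask_bmp(path)), region = region,
                subject_id = subject_id)
}

#' Write a binary mask as a PNG for visual inspection
#'
#' Debug output: ROI pixels white, background black.
#'
#' @param mask a [binary_mask()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for write_mask_png()")
  }
  png::writePNG(mask$values, path)
  invisible(path)
}
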