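#' Image grids
#'
#' Throughout oritune an image is a plain numeric matrix of luminance values
#' on a nominal \[0, 1\] scale: rows run down the picture (the vertical image
#' axis), columns run across it. `as_imagegrid()` validates a matrix and is
#' called by every image operation.
#'
#' @param img numeric matrix of luminance values.
#' @return the validated matrix, invisibly unchanged.
#' @export
as_imagegrid <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("image must be a numeric matrix", call. = FALSE)
  if (nrow(img) < 2L || ncol(img) < 2L)
    stop("image must be at least 2 x 2", call. = FALSE)
  if (!all(is.finite(img)))
    stop("image contains non-finite values", call. = FALSE)
  img
}

#' Pad an image by mirror reflection
#'
#' Extends the image by `pad_px` pixels on every side with the mirror
#' reflection of the adjacent interior, the usual guard against wrap-around
#' border artefacts when filtering in the Fourier domain. The edge row/column
#' is not duplicated (whole-sample symmetric reflection), so the reflection is
#' only defined for `pad_px < min(dim(img))`.
#'
#' @param img numeric matrix, see [as_imagegrid()].
#' @param pad_px non-negative integer number of pixels to add on each side.
#' @return a `(nrow + 2 pad) x (ncol + 2 pad)` matrix whose central region is
#'   `img` exactly.
#' @examples
#' dim(mirror_pad(matrix(0, 302, 309), 100))  # 502 x 509
#' @export
mirror_pad <- function(img, pad_px) {
  img <- as_imagegrid(img)
  pad_px <- as.integer(pad_px)
  if (length(pad_px) != 1L || is.na(pad_px) || pad_px < 0L)
    stop("pad_px must be a single non-negative integer", call. = FALSE)
  if (pad_px >= min(dim(img)))
    stop("pad_px exceeds image extent: need pad_px < min(dim(img))",
         call. = FALSE)
  if (pad_px == 0L) return(img)
  ridx <- c((pad_px + 1L):2L, seq_len(nrow(img)), (nrow(img) - 1L):(nrow(img) - pad_px))
  cidx <- c((pad_px + 1L):2L, seq_len(ncol(img)), (ncol(img) - 1L):(ncol(img) - pad_px))
  img[ridx, cidx]
}

#' Crop the central region of a padded image
#'
#' Inverse of [mirror_pad()]: removes `pad_px` pixels from every side.
#'
#' @inheritParams mirror_pad
#' @export
crop_pad <- function(img, pad_px) {
  img <- as_imagegrid(img)
  pad_px <- as.integer(pad_px)
  if (pad_px == 0L) return(img)
  if (pad_px < 0L || 2L * pad_px >= min(dim(img)))
    stop("pad_px incompatible with image size", call. = FALSE)
  img[(pad_px + 1L):(nrow(img) - pad_px), (pad_px + 1L):(ncol(img) - pad_px)]
}

#' Set mean luminance and RMS contrast
#'
#' Affine renormalization of an image to an exact mean luminance and RMS
#' contrast: `out = (img - mean(img)) / rms(img) * target_rms + target_mean`.
#' RMS contrast is the population standard deviation of luminance about the
#' mean, i.e. `sqrt(mean((img - mean(img))^2))`.
#'
#' Stimuli are normalized twice in the filtering pipeline: to (0, 1) before
#' the Fourier transform, and to the image-set statistics (0.5, 0.12) after
#' filtering.
#'
#' @param img numeric matrix.
#' @param target_mean desired mean luminance.
#' @param target_rms desired RMS contrast (must be > 0).
#' @return matrix with mean and RMS contrast equal to the targets to within
#'   1e-9.
#' @export
normalize_image <- function(img, target_mean, target_rms) {
  img <- as_imagegrid(img)
  if (target_rms <= 0) stop("target_rms must be positive", call. = FALSE)
  m <- mean(img)
  s <- sqrt(mean((img - m)^2))
  if (s < 1e-12)
    stop("degenerate image: zero variance, cannot set RMS contrast",
         call. = FALSE)
  (img - m) / s * target_rms + target_mean
}

#' RMS contrast of an image
#' @param img numeric matrix.
#' @return population standard deviation of luminance about the mean.
#' @export
rms_contrast <- function(img) {
  img <- as_imagegrid(img)
  sqrt(mean((img - mean(img))^2))
}

#' Proportion of clipped pixels
#'
#' Fraction of pixels falling outside the displayable luminance range
#' (below `lo` or above `hi`). Stimulus generation asserts this stays
#' below 3\% per image.
#'
#' @param img numeric matrix.
#' @param lo,hi range bounds, default the nominal \[0, 1\] luminance scale.
#' @export
clipped_fraction <- function(img, lo = 0, hi = 1) {
  img <- as_imagegrid(img)
  if (lo >= hi) stop("lo must be < hi", call. = FALSE)
  mean(img < lo | img > hi)
}

#' Clip an image to a luminance range
#' @inheritParams clipped_fraction
#' @export
clip_image <- function(img, lo = 0, hi = 1) {
  img <- as_imagegrid(img)
  img[img < lo] <- lo
  img[img > hi] <- hi
  img
}

#' Contrast negation
#'
#' Reverses contrast polarity by reflecting luminance about `mean_ref`
#' (default 0.5, the equalized mean): `out = 2 * mean_ref - img`, i.e.
#' `1 - img` on the equalized scale. Mean luminance and RMS contrast are
#' preserved and the operation is an involution. In the stimulus pipeline
#' negation is applied after filtering and luminance/contrast equalization
#' but before the elliptical aperture is blended.
#'
#' @param img numeric matrix (nominally equalized to mean `mean_ref`).
#' @param mean_ref luminance value about which to reflect.
#' @export
negate_image <- function(img, mean_ref = 0.5) {
  img <- as_imagegrid(img)
  2 * mean_ref - img
}

#' Picture-plane inversion
#'
#' Rotates the image 180 degrees in the picture plane (reversal of both
#' axes). The pixel multiset, mean and RMS contrast are unchanged; the
#' operation is an involution and commutes with [negate_image()].
#'
#' @param img numeric matrix.
#' @export
invert_image <- function(img) {
  img <- as_imagegrid(img)
  img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), drop = FALSE]
}

#' Read / write images as PNG
#'
#' Lossy only through 16-bit quantization; luminance is clipped to \[0, 1\]
#' on write.
#'
#' @param img numeric matrix.
#' @param path file path.
#' @export
write_image_png <- function(img, path) {
  img <- clip_image(as_imagegrid(img))
  png::writePNG(img, target = path, dpi = NULL)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  as_imagegrid(x)
}
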