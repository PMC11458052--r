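#' Elliptical aperture mask from an image set
#'
#' Builds the grey elliptical aperture that hides background, hair and neck:
#' the images are averaged, pixels deviating from the background grey by more
#' than `threshold` define the face region, and the smallest centered ellipse
#' covering that region (axes scaled from the region's half-ranges about its
#' centroid) becomes the visible area. The edge is softened with a cosine
#' ramp of `ramp_px` pixels.
#'
#' @param images list of same-sized images.
#' @param background background grey level, default 0.5.
#' @param threshold absolute deviation from background that counts as face.
#' @param ramp_px width of the soft cosine edge, in pixels.
#' @return a mask matrix in \[0, 1\]: 1 inside the ellipse (face visible),
#'   0 outside (background grey).
#' @export
make_aperture_mask <- function(images, background = 0.5, threshold = 0.05,
                               ramp_px = 6) {
  if (!is.list(images) || length(images) == 0L)
    stop("images must be a nonempty list", call. = FALSE)
  dims <- lapply(images, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("all images must share dimensions", call. = FALSE)
  avg <- Reduce(`+`, lapply(images, as_imagegrid)) / length(images)
  face <- which(abs(avg - background) > threshold, arr.ind = TRUE)
  if (nrow(face) == 0L)
    stop("no pixels deviate from background; cannot fit aperture", call. = FALSE)
  cy <- mean(face[, 1L]); cx <- mean(face[, 2L])
  ry0 <- max(abs(face[, 1L] - cy)); rx0 <- max(abs(face[, 2L] - cx))
  ry0 <- max(ry0, 1); rx0 <- max(rx0, 1)
  s <- sqrt(max(((face[, 1L] - cy) / ry0)^2 + ((face[, 2L] - cx) / rx0)^2))
  ry <- s * ry0; rx <- s * rx0
  yy <- matrix(seq_len(nrow(avg)), nrow(avg), ncol(avg))
  xx <- matrix(seq_len(ncol(avg)), nrow(avg), ncol(avg), byrow = TRUE)
  r <- sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
  # distance (px) outside the ellipse boundary, approximated radially
  d <- (r - 1) * min(rx, ry)
  mask <- ifelse(d <= 0, 1, ifelse(d >= ramp_px, 0,
                                   0.5 * (1 + cos(pi * d / ramp_px))))
  mask
}

#' Blend an image with an aperture mask
#'
#' `mask * img + (1 - mask) * background`; applied after all luminance and
#' contrast equalization (and after negation, for negated stimuli).
#'
#' @param img image matrix.
#' @param mask mask from [make_aperture_mask()], same dimensions.
#' @param background background grey, default 0.5.
#' @export
blend_aperture <- function(img, mask, background = 0.5) {
  img <- as_imagegrid(img)
  if (!all(dim(img) == dim(mask)))
    stop("mask and image dimensions differ", call. = FALSE)
  mask * img + (1 - mask) * background
}
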