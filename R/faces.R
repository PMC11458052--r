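#' Synthetic face identities
#'
#' A procedural stand-in for photographs of familiar faces (synthetic by
#' construction and labelled as such): a bright elliptical head on a mid-grey
#' background carrying darker horizontal feature bands (brows, eyes, nose
#' shadow, mouth). This reproduces the face's characteristic vertical
#' alternation of light and dark — features darker than the surrounding skin —
#' which concentrates identity-bearing energy in the horizontal orientation
#' range.
#'
#' `face_identity_params()` samples one identity's feature geometry; images of
#' the same identity differ only by a small seeded jitter of band positions
#' and depths (different "photographs" of one person).
#'
#' @param seed integer seed for the identity draw.
#' @param jitter_sd per-image geometric jitter, as a fraction of head height.
#' @return a list of feature-geometry parameters (class `face_identity`).
#' @export
face_identity_params <- function(seed, jitter_sd = 0.02) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- list(
    head_ry_frac = stats::runif(1, 0.38, 0.45),   # head semi-axes, image fracs
    head_rx_frac = stats::runif(1, 0.30, 0.36),
    skin         = stats::runif(1, 0.62, 0.72),
    # band centers in head coordinates v = (y - cy)/ry, -1 = crown, 1 = chin
    brow_v  = stats::rnorm(1, -0.38, 0.03),
    eye_v   = stats::rnorm(1, -0.22, 0.03),
    nose_v  = stats::rnorm(1,  0.12, 0.03),
    mouth_v = stats::rnorm(1,  0.45, 0.03),
    # vertical band widths (head fracs) and luminance depths
    brow_sig  = stats::runif(1, 0.070, 0.110),
    eye_sig   = stats::runif(1, 0.090, 0.130),
    nose_sig  = stats::runif(1, 0.060, 0.090),
    mouth_sig = stats::runif(1, 0.080, 0.120),
    brow_depth  = stats::runif(1, 0.20, 0.30),
    eye_depth   = stats::runif(1, 0.25, 0.38),
    nose_depth  = stats::runif(1, 0.08, 0.14),
    mouth_depth = stats::runif(1, 0.18, 0.30),
    # horizontal band extents as fractions of the head semi-width
    brow_w = stats::runif(1, 0.90, 1.05),
    eye_w  = stats::runif(1, 0.85, 1.00),
    nose_w = stats::runif(1, 0.45, 0.55),
    mouth_w = stats::runif(1, 0.65, 0.80),
    # broad forehead-bright / chin-dark shading alternation
    shading = stats::runif(1, 0.10, 0.14),
    jitter_sd = jitter_sd)
  structure(p, class = "face_identity")
}

#' @rdname face_identity_params
#' @param n number of identities.
#' @export
sample_identities <- function(n, seed, jitter_sd = 0.02) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seeds, face_identity_params, jitter_sd = jitter_sd)
}

#' Render one synthetic face image
#'
#' Deterministic given `(identity, seed)`: the seed drives the per-image
#' jitter that distinguishes different pictures of the same identity.
#'
#' @param identity a [face_identity_params()] object.
#' @param seed integer per-image seed.
#' @param height_px,width_px image size in pixels (default 302 x 309).
#' @return an image matrix on the \[0, 1\] scale.
#' @export
generate_synthetic_face <- function(identity, seed,
                                    height_px = 302, width_px = 309) {
  stopifnot(inherits(identity, "face_identity"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  p <- identity
  j <- function(x) x + stats::rnorm(1, 0, p$jitter_sd)
  jd <- function(x) x * exp(stats::rnorm(1, 0, 4 * p$jitter_sd))

  cy <- height_px * 0.5; cx <- width_px * 0.5
  ry <- p$head_ry_frac * height_px; rx <- p$head_rx_frac * width_px
  yy <- matrix(seq_len(height_px), height_px, width_px)
  xx <- matrix(seq_len(width_px), height_px, width_px, byrow = TRUE)
  r <- sqrt(((yy - cy) / ry)^2 + ((xx - cx) / rx)^2)
  # soft head outline: ~8 px cosine ramp
  ramp <- 8 / min(rx, ry)
  head <- ifelse(r <= 1, 1, ifelse(r >= 1 + ramp, 0,
                                   0.5 * (1 + cos(pi * (r - 1) / ramp))))

  v <- (yy - cy) / ry                     # vertical head coordinate
  u <- (xx - cx) / rx                     # horizontal head coordinate
  band <- function(center_v, sig_v, depth, w_frac) {
    depth * exp(-(v - center_v)^2 / (2 * sig_v^2)) *
      exp(-u^2 / (2 * (w_frac / 1.6)^2))
  }
  features <- band(j(p$brow_v),  p$brow_sig,  jd(p$brow_depth),  p$brow_w) +
    band(j(p$eye_v),   p$eye_sig,   jd(p$eye_depth),   p$eye_w) +
    band(j(p$nose_v),  p$nose_sig,  jd(p$nose_depth),  p$nose_w) +
    band(j(p$mouth_v), p$mouth_sig, jd(p$mouth_depth), p$mouth_w)
  # smooth vertical light/dark alternation (bright forehead, darker chin)
  shading <- p$shading * cos(pi * v) * exp(-u^2 / (2 * 0.6^2))

  face <- p$skin - features + shading
  0.5 + head * (face - 0.5)
}

#' Render an identity-by-image set of synthetic faces
#'
#' @param identities list from [sample_identities()].
#' @param images_per_identity pictures per identity.
#' @param seed integer seed for the per-image jitters.
#' @inheritParams generate_synthetic_face
#' @return nested list `faces[[identity]][[image]]` of image matrices.
#' @export
render_face_set <- function(identities, images_per_identity = 3, seed = 1,
                            height_px = 302, width_px = 309) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max,
                             length(identities) * images_per_identity),
                  length(identities), images_per_identity)
  lapply(seq_along(identities), function(i)
    lapply(seq_len(images_per_identity), function(k)
      generate_synthetic_face(identities[[i]], seeds[i, k],
                              height_px = height_px, width_px = width_px)))
}
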