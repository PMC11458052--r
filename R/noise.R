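#' Noise mask specification
#'
#' Masks shown between the probe and target faces are Gaussian noise fields
#' with a 1/f amplitude spectrum, equalized to the luminance statistics of
#' the face stimuli (mean 0.5, RMS contrast 0.12).
#'
#' @param diameter_px side length of the (square) mask in pixels.
#' @param spectral_exponent amplitude falloff exponent: amplitude scales as
#'   1 / f^exponent, default 1 (pink noise).
#' @param target_mean,target_rms luminance statistics to match.
#' @export
noise_mask_spec <- function(diameter_px, spectral_exponent = 1,
                            target_mean = 0.5, target_rms = 0.12) {
  diameter_px <- as.integer(diameter_px)
  stopifnot(length(diameter_px) == 1L, diameter_px > 0L,
            spectral_exponent >= 0, target_rms > 0)
  structure(list(diameter_px = diameter_px,
                 spectral_exponent = spectral_exponent,
                 target_mean = target_mean, target_rms = target_rms),
            class = "noise_mask_spec")
}

#' Generate a 1/f noise mask
#'
#' Shapes a seeded Gaussian white-noise field in the Fourier domain so its
#' amplitude spectrum falls off as 1/f^`spectral_exponent` with radial
#' frequency, then renormalizes to the target mean and RMS contrast.
#' Deterministic given the seed.
#'
#' @param spec a [noise_mask_spec()].
#' @param seed integer RNG seed.
#' @return a `diameter_px` x `diameter_px` image.
#' @export
make_noise_mask <- function(spec, seed) {
  stopifnot(inherits(spec, "noise_mask_spec"))
  n <- spec$diameter_px
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  white <- matrix(stats::rnorm(n * n), n, n)
  f <- fft_freqs(n)
  r <- sqrt(outer(f^2, f^2, `+`))
  shape <- r
  shape[r > 0] <- 1 / r[r > 0]^spec$spectral_exponent
  shape[1L, 1L] <- 0  # mean set by normalization
  pink <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE)) / (n * n)
  normalize_image(pink, spec$target_mean, spec$target_rms)
}

# save/restore the global RNG state so seeded generators do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
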