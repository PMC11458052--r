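# shared fixtures and independent oracles, built in code at test time

# brute-force orientation filter: loops over every spectrum coefficient and
# multiplies it by the wrapped-Gaussian weight at that coefficient's
# orientation; independent of the vectorized implementation
brute_force_filter <- function(img, spec) {
  h <- nrow(img); w <- ncol(img)
  fr <- function(n) c(0:(ceiling(n / 2) - 1L), -(floor(n / 2)):-1L) / n
  fy <- fr(h); fx <- fr(w)
  FF <- stats::fft(img)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (r == 1L && c == 1L) next  # DC passes
      th <- (atan2(fy[r], fx[c]) * 180 / pi) %% 180
      FF[r, c] <- FF[r, c] * wrapped_gaussian_weight(th, spec)
    }
  }
  Re(stats::fft(FF, inverse = TRUE) / (h * w))
}

# horizontal-structure grating: luminance varies only along the vertical
# pixel axis (image-plane orientation label 90 degrees)
horizontal_grating <- function(h = 64, w = 64, cycles = 8) {
  matrix(rep(0.5 + 0.1 * sin(2 * pi * cycles * seq_len(h) / h), w), h, w)
}

small_face <- function(seed_id = 1, seed_img = 2, h = 96, w = 98) {
  generate_synthetic_face(face_identity_params(seed_id), seed_img,
                          height_px = h, width_px = w)
}

# small scored cohort, computed once per test run
scored_cohort <- local({
  cache <- NULL
  function(n_subjects = 8, seed = 42) {
    if (is.null(cache)) {
      trials <- simulate_cohort(n_subjects = n_subjects, seed = seed)
      cache <<- list(trials = trials, scores = score_trials(trials))
    }
    cache
  }
})

# the scaled-down recovery experiment shared by the acceptance checks:
# 21 subjects at the published population means, reduced MCMC
recovery_experiment <- local({
  cache <- NULL
  function(seed = 20240901) {
    if (is.null(cache)) {
      trials <- simulate_cohort(population_params(), n_subjects = 21,
                                seed = seed)
      scores <- score_trials(trials)
      fit <- fit_tuning_model(scores$effects,
                              mcmc = mcmc_config(n_chains = 4,
                                                 n_iterations = 1500,
                                                 n_warmup = 500,
                                                 seed = seed))
      cache <<- list(trials = trials, scores = scores, fit = fit)
    }
    cache
  }
})
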