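#' Gaussian tuning parameters
#'
#' The four-parameter Gaussian tuning curve used both generatively (observer
#' simulation) and inferentially (the hierarchical model):
#' `base + peak * exp(-(theta - loc)^2 / (2 sd^2))`. Peak location is the
#' orientation of the maximal effect, standard deviation its sharpness, peak
#' amplitude the peak-minus-base height, and base amplitude the
#' orientation-independent floor.
#'
#' @param peak_location degrees in \[0, 180).
#' @param standard_deviation degrees, > 0.
#' @param peak_amplitude,base_amplitude sensitivity units (d-prime or
#'   normalized d-prime).
#' @export
gaussian_tuning_params <- function(peak_location, standard_deviation,
                                   peak_amplitude, base_amplitude) {
  if (standard_deviation <= 0)
    stop("standard_deviation must be positive", call. = FALSE)
  structure(list(peak_location = peak_location,
                 standard_deviation = standard_deviation,
                 peak_amplitude = peak_amplitude,
                 base_amplitude = base_amplitude),
            class = "gaussian_tuning_params")
}

#' Population parameters for observer simulation
#'
#' Defines the generative population: a Gaussian orientation tuning of raw
#' d-prime for natural stimuli, Gaussian-tuned inversion and negation effect
#' curves that are *subtracted* from the natural curve, scalar full-spectrum
#' sensitivities per stimulus type, a response criterion, and log-normal
#' response-time parameters.
#'
#' Defaults: the effect-curve means are the published population posterior
#' means of the hierarchical Gaussian model (inversion: location 91.52, sd
#' 34.06, peak 1.11, base 1.20; negation: location 85.99, sd 39.39, peak
#' 1.18, base 0.53). The natural-condition raw-d-prime tuning (location 90,
#' sd 35, peak 1.2, base 1.6) is chosen so that simulated condition means
#' reproduce the observed ordering natural > negated > inverted with a
#' normalized-d-prime grand spread near 1, and so that expected sensitivity
#' stays above chance in every condition (as observed in the experiment's
#' retained participants) — the natural base shifts all three conditions
#' equally, leaving the effect curves themselves untouched. Between-subject
#' sds: 8 degrees (locations), 5 degrees (tuning widths), 0.25 (amplitudes).
#'
#' @param natural,inversion_effect,negation_effect [gaussian_tuning_params()]
#'   population means.
#' @param fullspectrum named numeric: raw d-prime at full spectrum per type.
#' @param sd_peak_location,sd_standard_deviation,sd_amplitude between-subject
#'   sds applied to every curve's parameters.
#' @param sd_fullspectrum between-subject sd of full-spectrum d-prime.
#' @param criterion_mean,criterion_sd signal-detection response criterion
#'   (bias; default off).
#' @param rt_log_mean,rt_log_sd log-normal RT parameters (log-milliseconds).
#' @param sd_rt_log_mean between-subject sd of `rt_log_mean`.
#' @param rt_outlier_rate probability a trial's RT is replaced by an extreme
#'   value (attentional lapse or anticipation).
#' @export
population_params <- function(
    natural = gaussian_tuning_params(90, 35, 1.2, 1.6),
    inversion_effect = gaussian_tuning_params(91.52, 34.06, 1.11, 1.20),
    negation_effect = gaussian_tuning_params(85.99, 39.39, 1.18, 0.53),
    fullspectrum = c(natural = 2.9, inverted = 1.2, negated = 1.8),
    sd_peak_location = 8, sd_standard_deviation = 5, sd_amplitude = 0.25,
    sd_fullspectrum = 0.3,
    criterion_mean = 0, criterion_sd = 0,
    rt_log_mean = log(900), rt_log_sd = 0.35, sd_rt_log_mean = 0.15,
    rt_outlier_rate = 0.02) {
  structure(list(natural = natural, inversion_effect = inversion_effect,
                 negation_effect = negation_effect,
                 fullspectrum = fullspectrum,
                 sd_peak_location = sd_peak_location,
                 sd_standard_deviation = sd_standard_deviation,
                 sd_amplitude = sd_amplitude,
                 sd_fullspectrum = sd_fullspectrum,
                 criterion_mean = criterion_mean, criterion_sd = criterion_sd,
                 rt_log_mean = rt_log_mean, rt_log_sd = rt_log_sd,
                 sd_rt_log_mean = sd_rt_log_mean,
                 rt_outlier_rate = rt_outlier_rate),
            class = "population_params")
}

#' Draw a cohort of observers
#'
#' Subject-level tuning parameters are normal deviations around the
#' population means; tuning standard deviations are truncated below at 1
#' degree to stay positive.
#'
#' @param pop a [population_params()] object.
#' @param n_subjects cohort size (the experiment retained 21 participants).
#' @param seed integer seed.
#' @return list of observer parameter lists (class `observer_params`), one
#'   per subject.
#' @export
draw_observers <- function(pop, n_subjects = 21, seed = 1) {
  stopifnot(inherits(pop, "population_params"), n_subjects >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draw_curve <- function(mu) {
    gaussian_tuning_params(
      peak_location = stats::rnorm(1, mu$peak_location, pop$sd_peak_location),
      standard_deviation = max(1, stats::rnorm(1, mu$standard_deviation,
                                               pop$sd_standard_deviation)),
      peak_amplitude = stats::rnorm(1, mu$peak_amplitude, pop$sd_amplitude),
      base_amplitude = stats::rnorm(1, mu$base_amplitude, pop$sd_amplitude))
  }
  lapply(seq_len(n_subjects), function(j) {
    structure(list(
      subject_id = sprintf("s%02d", j),
      natural = draw_curve(pop$natural),
      inversion_effect = draw_curve(pop$inversion_effect),
      negation_effect = draw_curve(pop$negation_effect),
      fullspectrum = stats::rnorm(3, pop$fullspectrum, pop$sd_fullspectrum) |>
        stats::setNames(names(pop$fullspectrum)),
      criterion = stats::rnorm(1, pop$criterion_mean, pop$criterion_sd),
      rt_log_mean = stats::rnorm(1, pop$rt_log_mean, pop$sd_rt_log_mean),
      rt_log_sd = pop$rt_log_sd,
      rt_outlier_rate = pop$rt_outlier_rate), class = "observer_params")
  })
}

#' Evaluate a Gaussian tuning curve with 180-degree wrapping
#'
#' @param theta_deg orientation(s), degrees.
#' @param params a [gaussian_tuning_params()] object.
#' @param wrap use the wrapped angular distance on the 180-degree orientation
#'   circle (generative model); the fitted model uses the unwrapped distance
#'   on the duplicated 0..180 grid.
#' @export
gaussian_tuning <- function(theta_deg, params, wrap = FALSE) {
  stopifnot(inherits(params, "gaussian_tuning_params"))
  d <- theta_deg - params$peak_location
  if (wrap) d <- (d + 90) %% 180 - 90
  params$base_amplitude +
    params$peak_amplitude * exp(-d^2 / (2 * params$standard_deviation^2))
}

#' Expected sensitivity of an observer in one condition
#'
#' Natural stimuli follow the observer's natural tuning curve g(theta);
#' inverted and negated conditions are g(theta) minus the corresponding
#' Gaussian-tuned effect curve (the analysis recovers the effects by the same
#' subtraction in the opposite direction). Full-spectrum conditions use the
#' scalar full-spectrum sensitivities. Negative expected d-prime can occur
#' after subtraction; it is clamped at 0 only when generating responses
#' (`clamp = TRUE`), never in analysis.
#'
#' @param obs an observer from [draw_observers()].
#' @param stimulus_type `"natural"`, `"inverted"` or `"negated"`.
#' @param filter orientation in degrees, or `"fullspectrum"`.
#' @param clamp clamp at 0 (for response generation).
#' @export
expected_dprime <- function(obs, stimulus_type, filter, clamp = FALSE) {
  stopifnot(inherits(obs, "observer_params"))
  if (identical(as.character(filter), "fullspectrum")) {
    d <- unname(obs$fullspectrum[stimulus_type])
  } else {
    th <- as.numeric(as.character(filter))
    g_nat <- gaussian_tuning(th, obs$natural, wrap = TRUE)
    d <- switch(stimulus_type,
                natural = g_nat,
                inverted = g_nat - gaussian_tuning(th, obs$inversion_effect,
                                                   wrap = TRUE),
                negated = g_nat - gaussian_tuning(th, obs$negation_effect,
                                                  wrap = TRUE),
                stop("unknown stimulus_type", call. = FALSE))
  }
  if (clamp) d <- pmax(d, 0)
  d
}

#' Simulate same/different responses and response times
#'
#' Equal-variance signal-detection generative model: with expected
#' sensitivity d and criterion c, P(respond same | same pair) =
#' Phi(d/2 - c) and P(respond same | different pair) = Phi(-d/2 - c).
#' Response times are log-normal; with probability `rt_outlier_rate` a
#' trial's RT is replaced by an extreme value (a slow lapse near the 4400 ms
#' response deadline, or occasionally a fast anticipation).
#'
#' @param obs an observer from [draw_observers()].
#' @param schedule trial schedule from [build_schedule()].
#' @param seed integer seed.
#' @return the schedule with `response_same` (logical), `correct` (logical)
#'   and `rt` (milliseconds) appended.
#' @export
simulate_trials <- function(obs, schedule, seed = 1) {
  stopifnot(inherits(obs, "observer_params"), is.data.frame(schedule))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n <- nrow(schedule)
  d <- mapply(function(ty, flt) expected_dprime(obs, ty, flt, clamp = TRUE),
              schedule$stimulus_type, schedule$filter)
  p_same <- ifelse(schedule$is_same,
                   stats::pnorm(d / 2 - obs$criterion),
                   stats::pnorm(-d / 2 - obs$criterion))
  resp <- stats::runif(n) < p_same
  rt <- stats::rlnorm(n, obs$rt_log_mean, obs$rt_log_sd)
  out_idx <- which(stats::runif(n) < obs$rt_outlier_rate)
  if (length(out_idx)) {
    slow <- stats::runif(length(out_idx)) < 0.8
    rt[out_idx[slow]] <- stats::runif(sum(slow), 3200, 4400)
    rt[out_idx[!slow]] <- stats::runif(sum(!slow), 80, 200)
  }
  schedule$subject <- obs$subject_id
  schedule$response_same <- resp
  schedule$correct <- resp == schedule$is_same
  schedule$rt <- rt
  schedule
}

#' Simulate a full cohort
#'
#' Draws observers, builds each subject's pair pool and schedule, and
#' simulates all trials. Convenience wrapper used by the recovery and
#' calibration experiments.
#'
#' @inheritParams draw_observers
#' @param n_identities,images_per_identity face-set size for the pair pools.
#' @return data frame of trial records for all subjects.
#' @export
simulate_cohort <- function(pop = population_params(), n_subjects = 21,
                            seed = 1, n_identities = 10,
                            images_per_identity = 3) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  obs <- draw_observers(pop, n_subjects, seed = seed)
  seeds <- matrix(sample.int(.Machine$integer.max, 3L * n_subjects),
                  n_subjects, 3L)
  do.call(rbind, lapply(seq_len(n_subjects), function(j) {
    pairs <- build_pairs(n_identities, images_per_identity, seed = seeds[j, 1])
    sched <- build_schedule(pairs, seed = seeds[j, 2],
                            subject_id = obs[[j]]$subject_id)
    simulate_trials(obs[[j]], sched, seed = seeds[j, 3])
  }))
}
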