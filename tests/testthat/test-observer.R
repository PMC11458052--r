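test_that("Gaussian tuning curve closed forms", {
  p <- gaussian_tuning_params(90, 30, 2, 1.5)
  expect_equal(gaussian_tuning(90, p), 3.5)
  expect_equal(gaussian_tuning(c(60, 120), p), rep(1.5 + 2 * exp(-1 / 2), 2))
  expect_equal(gaussian_tuning(90 + 1e6 * 30, p), 1.5)
  # published population means for the inversion effect, evaluated at 0 deg
  inv <- gaussian_tuning_params(91.52, 34.06, 1.11, 1.20)
  expect_equal(gaussian_tuning(0, inv), 1.23002616775, tolerance = 1e-9)
  # wrapped evaluation is periodic on the orientation circle
  expect_equal(gaussian_tuning(179, inv, wrap = TRUE),
               gaussian_tuning(-1, inv, wrap = TRUE))
  expect_error(gaussian_tuning_params(90, -2, 1, 1), "positive")
})

test_that("observer cohorts are reproducible and collapse at zero spread", {
  pop0 <- population_params(sd_peak_location = 0, sd_standard_deviation = 0,
                            sd_amplitude = 0, sd_fullspectrum = 0,
                            sd_rt_log_mean = 0)
  obs <- draw_observers(pop0, 3, seed = 1)
  expect_length(obs, 3)
  expect_equal(obs[[1]]$natural, obs[[3]]$natural)
  expect_equal(obs[[2]]$inversion_effect$base_amplitude, 1.20)
  pop <- population_params()
  expect_equal(draw_observers(pop, 21, seed = 9),
               draw_observers(pop, 21, seed = 9))
})

test_that("expected sensitivity follows natural-minus-effect subtraction", {
  pop0 <- population_params(sd_peak_location = 0, sd_standard_deviation = 0,
                            sd_amplitude = 0, sd_fullspectrum = 0)
  obs <- draw_observers(pop0, 1, seed = 1)[[1]]
  # inversion effect at 90 deg with the published means ~ 2.31
  d_nat <- expected_dprime(obs, "natural", 90)
  d_inv <- expected_dprime(obs, "inverted", 90)
  expect_equal(d_nat - d_inv, 2.3089141, tolerance = 1e-4)
  # natural sensitivity peaks horizontally
  expect_gt(expected_dprime(obs, "natural", 90),
            expected_dprime(obs, "natural", 0))
  expect_equal(expected_dprime(obs, "natural", "fullspectrum"), 2.9)
  # clamping applies only on request
  hard <- draw_observers(population_params(
    natural = gaussian_tuning_params(90, 35, 0.2, 0.2),
    sd_peak_location = 0, sd_standard_deviation = 0, sd_amplitude = 0,
    sd_fullspectrum = 0), 1, seed = 1)[[1]]
  expect_lt(expected_dprime(hard, "inverted", 90), 0)
  expect_equal(expected_dprime(hard, "inverted", 90, clamp = TRUE), 0)
})

test_that("simulated responses follow the equal-variance SDT model", {
  pairs <- build_pairs(seed = 4)
  sched <- build_schedule(pairs, seed = 5)
  pop0 <- population_params(natural = gaussian_tuning_params(90, 35, 0, 0),
                            inversion_effect = gaussian_tuning_params(90, 35, 0, 0),
                            negation_effect = gaussian_tuning_params(90, 35, 0, 0),
                            fullspectrum = c(natural = 0, inverted = 0, negated = 0),
                            sd_peak_location = 0, sd_standard_deviation = 0,
                            sd_amplitude = 0, sd_fullspectrum = 0,
                            rt_outlier_rate = 0)
  obs <- draw_observers(pop0, 1, seed = 1)[[1]]
  tr <- simulate_trials(obs, sched, seed = 6)
  # d = 0, c = 0: chance responding
  expect_lt(abs(mean(tr$response_same) - 0.5), 0.05)
  expect_identical(simulate_trials(obs, sched, seed = 6), tr)
  # huge d: hit rate 1, false-alarm rate 0
  strong <- draw_observers(population_params(
    natural = gaussian_tuning_params(90, 35, 0, 50),
    fullspectrum = c(natural = 50, inverted = 50, negated = 50),
    sd_peak_location = 0, sd_standard_deviation = 0, sd_amplitude = 0,
    sd_fullspectrum = 0), 1, seed = 1)[[1]]
  tn <- simulate_trials(strong, sched[sched$stimulus_type == "natural", ],
                        seed = 7)
  expect_equal(mean(tn$response_same[tn$is_same]), 1)
  expect_equal(mean(tn$response_same[!tn$is_same]), 0)
})

test_that("log-linear d-prime is unbiased over simulated condition cells", {
  # Monte-Carlo oracle: 2000 replicates of a 30 same / 30 different cell at
  # the generative d of 1.8505, scored with the log-linear correction
  set.seed(123)
  d_true <- 1.85048911971
  hits <- rbinom(2000, 30, pnorm(d_true / 2))
  fas <- rbinom(2000, 30, pnorm(-d_true / 2))
  d_hat <- loglinear_dprime(hits, fas, 30, 30)
  expect_lt(abs(mean(d_hat) - d_true), 0.05)
})

test_that("stronger inversion floor lowers inverted-condition accuracy", {
  pairs <- build_pairs(seed = 8)
  sched <- build_schedule(pairs, seed = 8)
  sched <- sched[sched$stimulus_type == "inverted", ]
  acc <- sapply(c(0.5, 2.0), function(b) {
    pop <- population_params(
      inversion_effect = gaussian_tuning_params(91.52, 34.06, 1.11, b),
      sd_peak_location = 0, sd_standard_deviation = 0, sd_amplitude = 0,
      sd_fullspectrum = 0)
    obs <- draw_observers(pop, 1, seed = 2)[[1]]
    mean(simulate_trials(obs, sched, seed = 3)$correct)
  })
  expect_gt(acc[1], acc[2])
})
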