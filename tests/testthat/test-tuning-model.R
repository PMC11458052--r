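test_that("credible intervals are equal-tailed quantile intervals", {
  ci <- credible_interval(1:1000, 0.89)
  expect_equal(ci, c(55.945, 945.055))
  expect_equal(credible_interval(c(5, 1, 9), 1), c(1, 9))
  # symmetric draws give an interval symmetric about the median
  x <- c(-(500:1), 500:1)
  ci2 <- credible_interval(x, 0.89)
  expect_equal(ci2[1], -ci2[2])
  expect_error(credible_interval(numeric(0)), "empty")
  expect_error(credible_interval(1:50, 0.89), "100")
  expect_error(credible_interval(1:1000, 1.2), "level")
})

test_that("interval overlap implements the CrI decision rule", {
  # the published base-amplitude CrIs separate ...
  expect_false(interval_overlap(c(0.99, 1.42), c(0.25, 0.80)))
  # ... while the peak-location CrIs overlap
  expect_true(interval_overlap(c(83.40, 98.56), c(78.01, 93.31)))
  expect_true(interval_overlap(c(1, 2), c(1, 2)))
  expect_true(interval_overlap(c(1, 2), c(2, 3)))
  expect_false(interval_overlap(c(1, 2), c(2.0001, 3)))
})

test_that("noise-free effect curves are recovered to high precision", {
  # all subjects share one true parameter set; residual sd ~ 0
  truth <- list(loc = c(92, 86), sdp = c(34, 39), peak = c(1.1, 1.2),
                base = c(1.2, 0.5))
  grid <- expand.grid(subject = sprintf("s%02d", 1:6),
                      filter_deg = seq(0, 180, 30),
                      stringsAsFactors = FALSE)
  g <- function(th, k) truth$base[k] + truth$peak[k] *
    exp(-(th - truth$loc[k])^2 / (2 * truth$sdp[k]^2))
  set.seed(31)
  eff <- data.frame(grid,
                    inversion_effect = g(grid$filter_deg, 1) +
                      rnorm(nrow(grid), 0, 0.005),
                    negation_effect = g(grid$filter_deg, 2) +
                      rnorm(nrow(grid), 0, 0.005))
  fit <- suppressWarnings(
    fit_tuning_model(eff, mcmc = mcmc_config(2, 2000, 600, seed = 2)))
  s <- fit$summary
  for (k in 1:2) {
    ty <- c("inversion", "negation")[k]
    expect_lt(abs(s$mean[s$parameter == "peak_location" &
                           s$effect_type == ty] - truth$loc[k]), 1)
    expect_lt(abs(s$mean[s$parameter == "standard_deviation" &
                           s$effect_type == ty] - truth$sdp[k]), 1)
    expect_lt(abs(s$mean[s$parameter == "peak_amplitude" &
                           s$effect_type == ty] - truth$peak[k]), 0.05)
    expect_lt(abs(s$mean[s$parameter == "base_amplitude" &
                           s$effect_type == ty] - truth$base[k]), 0.05)
  }
  # posterior predictive ribbon: contains the mean curve, peaks near the
  # posterior-mean location, and is narrow in the noiseless limit
  pp <- posterior_predict_curve(fit, seq(0, 180, 5))
  expect_true(all(pp$lower <= pp$mean & pp$mean <= pp$upper))
  inv <- pp[pp$effect_type == "inversion", ]
  expect_lt(abs(inv$theta[which.max(inv$mean)] -
                  s$mean[s$parameter == "peak_location" &
                           s$effect_type == "inversion"]), 5)
  expect_lt(max(pp$upper - pp$lower), 0.25)
  # diagnostics are reported for every population parameter
  expect_true(all(c("rhat", "ess", "divergences") %in%
                    names(fit$diagnostics)))
  expect_equal(nrow(fit$diagnostics), 9L)
})

test_that("fits are reproducible under a fixed seed", {
  sc <- scored_cohort()
  eff <- sc$scores$effects
  cfg <- mcmc_config(2, 400, 200, seed = 77)
  f1 <- suppressWarnings(fit_tuning_model(eff, mcmc = cfg))
  f2 <- suppressWarnings(fit_tuning_model(eff, mcmc = cfg))
  expect_equal(f1$summary, f2$summary)
  expect_equal(f1$subject, f2$subject)
})

test_that("prior-predictive tuning curves mostly peak around horizontal", {
  # intercept prior normal(90, 20): at least ~60% of prior draws peak
  # within [50, 130] degrees
  set.seed(5)
  pr <- tuning_priors()
  locs <- rnorm(4000, pr$intercept_mean[1], pr$intercept_sd[1])
  expect_gte(mean(locs >= 50 & locs <= 130), 0.6)
})
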