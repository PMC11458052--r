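test_that("RT outliers are flagged per subject by the 2.5-sd rule", {
  tr <- data.frame(subject = "s1", rt = c(rep(500, 99), 5000))
  out <- filter_rt_outliers(tr)
  expect_equal(sum(out$excluded), 1L)
  expect_true(out$excluded[100])
  # zero variance: nothing excluded
  flat <- filter_rt_outliers(data.frame(subject = "s1", rt = rep(700, 10)))
  expect_false(any(flat$excluded))
  # rule applies within subject, single pass
  two <- data.frame(subject = rep(c("a", "b"), each = 100),
                    rt = c(rep(500, 99), 5000, rep(2000, 99), 12000))
  out2 <- filter_rt_outliers(two)
  expect_equal(which(out2$excluded), c(100L, 200L))
  expect_error(filter_rt_outliers(data.frame(subject = "a", rt = c(-1, 500))))
})

test_that("log-linear d-prime matches the inverse-normal oracle", {
  expect_equal(loglinear_dprime(25, 5, 30, 30), 1.85048911971,
               tolerance = 1e-9)
  # perfect performance stays finite: 2 * qnorm(30.5/31)
  expect_equal(loglinear_dprime(30, 0, 30, 30), 4.28239624194,
               tolerance = 1e-9)
  # equal hit and false-alarm rates give d' = 0 at equal n
  expect_equal(loglinear_dprime(12, 12, 30, 30), 0)
  # brute-force enumeration oracle over all (hits, fa) cells at n = 5/5
  for (h in 0:5) for (fa in 0:5)
    expect_equal(loglinear_dprime(h, fa, 5, 5),
                 qnorm((h + 0.5) / 6) - qnorm((fa + 0.5) / 6),
                 tolerance = 1e-9)
  expect_error(loglinear_dprime(1, 1, 0, 5), "positive")
  expect_error(loglinear_dprime(6, 0, 5, 5), "range")
})

test_that("sensitivity table aggregates hits and false alarms per cell", {
  sc <- scored_cohort()
  tab <- sensitivity_table(filter_rt_outliers(sc$trials))
  expect_true(all(tab$n_same + tab$n_diff <= 60))
  expect_equal(nrow(tab), 8 * 3 * 7)
  expect_true(all(is.finite(tab$dprime)))
  # recompute one cell by hand
  t1 <- sc$trials[!filter_rt_outliers(sc$trials)$excluded, ]
  cell <- t1[t1$subject == "s01" & t1$stimulus_type == "natural" &
               t1$filter == "90", ]
  row <- tab[tab$subject == "s01" & tab$stimulus_type == "natural" &
               tab$filter == "90", ]
  expect_equal(row$hits, sum(cell$is_same & cell$response_same))
  expect_equal(row$false_alarms, sum(!cell$is_same & cell$response_same))
})

test_that("grand z-normalization: mean 0, sd 1, affine-invariant, monotone", {
  sc <- scored_cohort()
  tab <- sensitivity_table(filter_rt_outliers(sc$trials))
  z <- normalize_sensitivity(tab)
  expect_lt(abs(mean(z$norm_dprime)), 1e-9)
  expect_lt(abs(sd(z$norm_dprime) - 1), 1e-9)
  shifted <- tab
  shifted$dprime <- 3 * tab$dprime + 2
  expect_equal(normalize_sensitivity(shifted)$norm_dprime, z$norm_dprime,
               tolerance = 1e-12)
  expect_equal(order(z$norm_dprime), order(tab$dprime))
  # per-subject scope standardizes within subject
  zs <- normalize_sensitivity(tab, scope = "subject")
  m <- tapply(zs$norm_dprime, zs$subject, mean)
  expect_true(all(abs(m) < 1e-9))
  const <- tab; const$dprime <- 1
  expect_error(normalize_sensitivity(const), "degenerate")
})

test_that("circular duplication copies 0-degree cells to 180, idempotently", {
  sc <- scored_cohort()
  z <- normalize_sensitivity(sensitivity_table(filter_rt_outliers(sc$trials)))
  dup <- duplicate_circular(z)
  expect_setequal(unique(dup$filter),
                  c("0", "30", "60", "90", "120", "150", "180", "fullspectrum"))
  z0 <- dup[dup$filter == "0", ]
  z180 <- dup[dup$filter == "180", ]
  key <- function(d) paste(d$subject, d$stimulus_type)
  expect_equal(z180$norm_dprime[order(key(z180))],
               z0$norm_dprime[order(key(z0))])
  expect_equal(duplicate_circular(dup), dup)
  expect_error(duplicate_circular(z[z$filter != "0", ]), "0-degree")
})

test_that("effect curves subtract conditions and exclude full spectrum", {
  sc <- scored_cohort()
  eff <- sc$scores$effects
  expect_setequal(unique(eff$filter_deg), seq(0, 180, 30))
  expect_equal(nrow(eff), 8 * 7)
  # value at 180 equals value at 0 (the duplicated cell)
  e0 <- eff[eff$filter_deg == 0, ]
  e180 <- eff[eff$filter_deg == 180, ]
  expect_equal(e180$inversion_effect[order(e180$subject)],
               e0$inversion_effect[order(e0$subject)])
  # antisymmetry: swapping the operands flips the sign
  tab <- sc$scores$sensitivity
  swapped <- tab
  swapped$stimulus_type[tab$stimulus_type == "natural"] <- "inverted"
  swapped$stimulus_type[tab$stimulus_type == "inverted"] <- "natural"
  eff2 <- compute_effects(swapped)
  expect_equal(eff2$inversion_effect, -eff$inversion_effect)
  # pipeline linearity: effects equal raw d-prime differences over the grand sd
  tabr <- sensitivity_table(filter_rt_outliers(sc$trials))
  S <- sd(tabr$dprime)
  raw <- duplicate_circular(tabr)
  wide <- reshape(raw[raw$filter != "fullspectrum",
                      c("subject", "stimulus_type", "filter", "dprime")],
                  idvar = c("subject", "filter"), timevar = "stimulus_type",
                  direction = "wide")
  ord <- order(wide$subject, as.numeric(wide$filter))
  expect_equal(eff$inversion_effect,
               ((wide$dprime.natural - wide$dprime.inverted) / S)[ord],
               tolerance = 1e-12)
  # identical conditions give an identically zero effect
  same <- tab
  same$norm_dprime[same$stimulus_type == "inverted"] <-
    same$norm_dprime[same$stimulus_type == "natural"]
  expect_true(all(compute_effects(same)$inversion_effect == 0))
})

test_that("simulated cohort shows a horizontally peaked inversion effect", {
  sc <- scored_cohort()
  eff <- sc$scores$effects
  m90 <- mean(eff$inversion_effect[eff$filter_deg == 90])
  m0 <- mean(eff$inversion_effect[eff$filter_deg == 0])
  expect_gt(m90, m0)
})
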