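#' Priors for the hierarchical Gaussian tuning model
#'
#' Normal priors on the population intercepts and effect-type slopes of the
#' four Gaussian parameters, exponential priors on the between-subject
#' random-effect sds, and an exponential prior on the residual sd. The
#' defaults are the model's published prior table: intercepts
#' normal(90, 20), normal(35, 20), normal(1.5, 1), normal(1.5, 1) for peak
#' location, standard deviation, peak amplitude and base amplitude; slopes
#' normal(0, 20), normal(0, 30), normal(0, 1.5), normal(0, 1.5); random-effect
#' rates exponential(0.1), exponential(0.1), exponential(0.1),
#' exponential(0.05). The residual-sd prior (exponential(1)) and the uniform
#' prior on the random-effect correlations are choices of this package.
#'
#' @param intercept_mean,intercept_sd,slope_mean,slope_sd numeric length-4
#'   vectors in the order (peak_location, standard_deviation, peak_amplitude,
#'   base_amplitude).
#' @param ranef_rate exponential rates of the random-effect sd priors.
#' @param residual_rate exponential rate of the residual sd prior.
#' @export
tuning_priors <- function(intercept_mean = c(90, 35, 1.5, 1.5),
                          intercept_sd = c(20, 20, 1, 1),
                          slope_mean = c(0, 0, 0, 0),
                          slope_sd = c(20, 30, 1.5, 1.5),
                          ranef_rate = c(0.1, 0.1, 0.1, 0.05),
                          residual_rate = 1) {
  stopifnot(length(intercept_mean) == 4, length(intercept_sd) == 4,
            length(slope_mean) == 4, length(slope_sd) == 4,
            length(ranef_rate) == 4,
            all(intercept_sd > 0), all(slope_sd > 0), all(ranef_rate > 0),
            residual_rate > 0)
  structure(list(intercept_mean = intercept_mean, intercept_sd = intercept_sd,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 ranef_rate = ranef_rate, residual_rate = residual_rate),
            class = "tuning_priors")
}

#' MCMC configuration
#'
#' The published fit used 4 chains of 6,000 iterations each with 2,000
#' warmup. `mcmc_config()` defaults to a reduced schedule (4 chains, 1,500
#' iterations, 500 warmup) adequate for the simulation experiments here;
#' pass the full schedule for production fits.
#'
#' @param n_chains number of chains (>= 2).
#' @param n_iterations total iterations per chain (warmup included).
#' @param n_warmup warmup (adaptation + burn-in) iterations per chain.
#' @param seed integer seed; chain RNGs are derived from it.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 1500, n_warmup = 500,
                        seed = 1) {
  stopifnot(n_chains >= 2, n_warmup < n_iterations, n_warmup >= 2)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed)), class = "mcmc_config")
}

.param_names <- c("peak_location", "standard_deviation", "peak_amplitude",
                  "base_amplitude")
.effect_types <- c("inversion", "negation")

.tuning_model_string <- "
model {
  for (i in 1:N) {
    mu[i] <- par[s[i], t[i], 4] + par[s[i], t[i], 3] *
             exp(-pow(theta[i] - par[s[i], t[i], 1], 2) /
                 (2 * pow(par[s[i], t[i], 2], 2)))
    y[i] ~ dnorm(mu[i], tau_res)
  }
  # hierarchically centered random effects: subject-level (intercept, slope)
  # pairs are drawn around the population pair, which mixes far better than
  # the offset parameterization under conditional (Gibbs-type) sampling
  for (j in 1:J) { for (k in 1:2) { for (p in 1:4) {
    par[j, k, p] <- v[p, j, 1] + v[p, j, 2] * (k - 1)
  } } }
  for (p in 1:4) {
    b[p, 1] ~ dnorm(int_mean[p], int_prec[p])
    b[p, 2] ~ dnorm(slp_mean[p], slp_prec[p])
    sd_re[p, 1] ~ dexp(re_rate[p])
    sd_re[p, 2] ~ dexp(re_rate[p])
    rho[p] ~ dunif(-1, 1)
    Sig[p, 1, 1] <- pow(sd_re[p, 1], 2)
    Sig[p, 2, 2] <- pow(sd_re[p, 2], 2)
    Sig[p, 1, 2] <- rho[p] * sd_re[p, 1] * sd_re[p, 2]
    Sig[p, 2, 1] <- Sig[p, 1, 2]
    Om[p, 1:2, 1:2] <- inverse(Sig[p, 1:2, 1:2])
    for (j in 1:J) { v[p, j, 1:2] ~ dmnorm(b[p, 1:2], Om[p, 1:2, 1:2]) }
  }
  tau_res <- pow(sigma_res, -2)
  sigma_res ~ dexp(res_rate)
}"

# run a JAGS model and return draws + diagnostics; shared by the tuning model
# and the GLMM
.run_jags <- function(model_string, data, monitor, mcmc, inits = NULL) {
  init_list <- lapply(seq_len(mcmc$n_chains), function(ch) {
    ini <- if (is.null(inits)) list() else inits
    ini$.RNG.name <- "base::Mersenne-Twister"
    # derive per-chain seeds in double precision: 32-bit integer arithmetic
    # would overflow for large user seeds
    ini$.RNG.seed <- as.integer((as.numeric(mcmc$seed) * 1000 + ch) %%
                                  2147483646) + 1L
    ini
  })
  n_adapt <- max(100L, mcmc$n_warmup %/% 2L)
  n_burn <- max(0L, mcmc$n_warmup - n_adapt)
  model <- rjags::jags.model(textConnection(model_string), data = data,
                             inits = init_list, n.chains = mcmc$n_chains,
                             n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) stats::update(model, n_burn)
  draws <- rjags::coda.samples(model, variable.names = monitor,
                               n.iter = mcmc$n_iterations - mcmc$n_warmup)
  draws
}

.diagnose <- function(draws) {
  mat <- as.matrix(draws)
  keep <- apply(mat, 2, function(x) stats::var(x) > 0)
  rhat <- rep(NA_real_, ncol(mat))
  names(rhat) <- colnames(mat)
  if (any(keep)) {
    gd <- try(coda::gelman.diag(draws[, colnames(mat)[keep], drop = FALSE],
                                multivariate = FALSE, autoburnin = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat[keep] <- gd$psrf[, 1]
  }
  ess <- coda::effectiveSize(draws)
  data.frame(parameter = colnames(mat), rhat = rhat,
             ess = as.numeric(ess[colnames(mat)]),
             row.names = NULL)
}

#' Fit the hierarchical Gaussian tuning model
#'
#' Fits the Bayesian nonlinear mixed-effects model of the inversion and
#' negation effect curves jointly: each of the four Gaussian parameters is
#' modelled as intercept + effect-type slope (treatment coding, inversion as
#' reference) with correlated per-subject intercept/slope deviations
#' (unstructured 2x2 covariance per parameter, independent across
#' parameters), and a single Gaussian residual sd shared across effect
#' types. Sampling uses JAGS; convergence is assessed with split-free Rhat
#' and effective sample size (divergent-transition counts do not exist for
#' JAGS's conditional samplers and are reported as NA). A fit with any
#' population-parameter Rhat above 1.01 is flagged, with a warning, in
#' `$diagnostics` — never silently accepted.
#'
#' @param effects effect curves from [compute_effects()] (subjects x filters
#'   0..180, both effect types).
#' @param priors a [tuning_priors()] object.
#' @param mcmc an [mcmc_config()] object.
#' @return an object of class `tuning_fit`: `summary` (population-level
#'   posterior mean/median/89\% CrI per Gaussian parameter x effect type),
#'   `subject` (posterior means of subject-level parameters),
#'   `draws` (matrix of population-level draws, columns
#'   `<parameter>.<effect_type>` plus `sigma_res`), `diagnostics`,
#'   `converged`, and the inputs.
#' @export
fit_tuning_model <- function(effects, priors = tuning_priors(),
                             mcmc = mcmc_config()) {
  stopifnot(inherits(priors, "tuning_priors"), inherits(mcmc, "mcmc_config"))
  need <- c("subject", "filter_deg", "inversion_effect", "negation_effect")
  stopifnot(all(need %in% names(effects)))
  subjects <- sort(unique(effects$subject))
  if (length(subjects) < 2L) stop("need at least 2 subjects", call. = FALSE)

  long <- rbind(
    data.frame(subject = effects$subject, theta = effects$filter_deg,
               type = 1L, y = effects$inversion_effect),
    data.frame(subject = effects$subject, theta = effects$filter_deg,
               type = 2L, y = effects$negation_effect))
  long$sidx <- match(long$subject, subjects)

  data <- list(N = nrow(long), J = length(subjects), y = long$y,
               s = long$sidx, t = long$type, theta = long$theta,
               int_mean = priors$intercept_mean,
               int_prec = 1 / priors$intercept_sd^2,
               slp_mean = priors$slope_mean,
               slp_prec = 1 / priors$slope_sd^2,
               re_rate = priors$ranef_rate,
               res_rate = priors$residual_rate)
  J <- length(subjects)
  v0 <- array(0, c(4, J, 2))
  v0[, , 1] <- priors$intercept_mean
  v0[, , 2] <- priors$slope_mean
  inits <- list(b = cbind(priors$intercept_mean, priors$slope_mean),
                v = v0, sigma_res = 1,
                sd_re = cbind(c(5, 5, 0.5, 0.5), c(5, 5, 0.5, 0.5)),
                rho = rep(0, 4))
  draws <- .run_jags(.tuning_model_string, data,
                     monitor = c("b", "sd_re", "rho", "sigma_res", "par"),
                     mcmc = mcmc, inits = inits)
  mat <- as.matrix(draws)

  # population-level parameter draws per effect type
  pop <- list()
  for (p in 1:4) {
    b1 <- mat[, sprintf("b[%d,1]", p)]
    b2 <- mat[, sprintf("b[%d,2]", p)]
    pop[[paste0(.param_names[p], ".inversion")]] <- b1
    pop[[paste0(.param_names[p], ".negation")]] <- b1 + b2
  }
  pop$sigma_res <- mat[, "sigma_res"]
  pop <- do.call(cbind, pop)

  summ <- do.call(rbind, lapply(seq_len(4), function(p) {
    do.call(rbind, lapply(1:2, function(k) {
      x <- pop[, paste0(.param_names[p], ".", .effect_types[k])]
      ci <- credible_interval(x, 0.89)
      data.frame(parameter = .param_names[p], effect_type = .effect_types[k],
                 median = stats::median(x), mean = mean(x),
                 cri_lower = ci[1], cri_upper = ci[2])
    }))
  }))

  subject_est <- expand.grid(subject = subjects, effect_type = .effect_types,
                             parameter = .param_names,
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
  subject_est$estimate <- mapply(function(sub, ty, par) {
    j <- match(sub, subjects); k <- match(ty, .effect_types)
    p <- match(par, .param_names)
    mean(mat[, sprintf("par[%d,%d,%d]", j, k, p)])
  }, subject_est$subject, subject_est$effect_type, subject_est$parameter)

  diag_pop <- .diagnose(draws[, c(sprintf("b[%d,1]", 1:4),
                                  sprintf("b[%d,2]", 1:4), "sigma_res"),
                              drop = FALSE])
  diag_pop$divergences <- NA_integer_
  converged <- all(is.finite(diag_pop$rhat)) && all(diag_pop$rhat < 1.01)
  if (!converged)
    warning("tuning model: Rhat > 1.01 for some population parameters; ",
            "inspect $diagnostics", call. = FALSE)

  structure(list(summary = summ, subject = subject_est, draws = pop,
                 diagnostics = diag_pop, converged = converged,
                 priors = priors, mcmc = mcmc, data = long),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  cat("Hierarchical Gaussian tuning model fit\n")
  cat(sprintf("  %d subjects, %d observations, %d chains x %d iterations\n",
              max(x$data$sidx), nrow(x$data), x$mcmc$n_chains,
              x$mcmc$n_iterations))
  cat(sprintf("  converged (all pop. Rhat < 1.01): %s\n\n", x$converged))
  s <- x$summary
  s[, c("median", "mean", "cri_lower", "cri_upper")] <-
    round(s[, c("median", "mean", "cri_lower", "cri_upper")], 2)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Equal-tailed credible interval
#'
#' @param draws numeric vector of posterior draws (>= 100 unless
#'   `level = 1`).
#' @param level interval mass in (0, 1\]; 0.89 is the decision level used for
#'   condition comparisons. `level = 1` returns the range.
#' @return numeric `c(lower, upper)` at the (1-level)/2 and 1-(1-level)/2
#'   quantiles.
#' @export
credible_interval <- function(draws, level = 0.89) {
  if (length(draws) == 0L) stop("empty draws", call. = FALSE)
  if (level <= 0 || level > 1) stop("level must be in (0, 1]", call. = FALSE)
  if (level == 1) return(range(draws))
  if (length(draws) < 100L)
    stop("need at least 100 draws for a quantile interval", call. = FALSE)
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a)))
}

#' Do two intervals overlap?
#'
#' The decision rule for condition comparisons: a difference is declared when
#' the 89\% credible intervals do *not* overlap.
#'
#' @param a,b numeric `c(lower, upper)`.
#' @export
interval_overlap <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L, a[1] <= a[2], b[1] <= b[2])
  max(a[1], b[1]) <= min(a[2], b[2])
}

#' Posterior predictive tuning curves
#'
#' Evaluates the population-level Gaussian tuning curve over a grid of
#' orientations for every posterior draw and summarizes pointwise with the
#' posterior mean and an 89\% credible ribbon, per effect type.
#'
#' @param fit a [fit_tuning_model()] result.
#' @param theta_grid orientations in degrees.
#' @param level ribbon mass.
#' @return data frame `effect_type`, `theta`, `mean`, `lower`, `upper`.
#' @export
posterior_predict_curve <- function(fit, theta_grid = seq(0, 180, by = 5),
                                    level = 0.89) {
  stopifnot(inherits(fit, "tuning_fit"))
  out <- lapply(.effect_types, function(ty) {
    loc <- fit$draws[, paste0("peak_location.", ty)]
    sdp <- fit$draws[, paste0("standard_deviation.", ty)]
    pk <- fit$draws[, paste0("peak_amplitude.", ty)]
    bs <- fit$draws[, paste0("base_amplitude.", ty)]
    vals <- vapply(theta_grid, function(th)
      bs + pk * exp(-(th - loc)^2 / (2 * sdp^2)), numeric(length(loc)))
    ci <- apply(vals, 2, credible_interval, level = level)
    data.frame(effect_type = ty, theta = theta_grid,
               mean = colMeans(vals), lower = ci[1, ], upper = ci[2, ])
  })
  do.call(rbind, out)
}
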