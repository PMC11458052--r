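#' Bayesian GLMM comparing stimulus types
#'
#' Hierarchical linear model of normalized sensitivity averaged over the six
#' orientation filters (full-spectrum trials excluded):
#' `normd' ~ stimulus_type + (stimulus_type | subject)`, with correlated
#' per-subject intercept and slope deviations. Fixed effects get effectively
#' flat normal(0, 100) priors; the random-effect covariance uses a scaled
#' inverse-Wishart prior (Wishart degrees of freedom d + 1, which makes the
#' marginal correlation priors uniform) with half-Student-t(3, 0, 2.5) scale
#' factors, and the residual sd a half-Student-t(3, 0, 2.5) prior —
#' the "default" weakly-informative choices of the reference Bayesian
#' regression ecosystem, made explicit here. Fit with JAGS.
#'
#' @param table normalized sensitivity table from [normalize_sensitivity()]
#'   (before or after [duplicate_circular()]; the duplicated 180-degree rows
#'   are dropped for the averaging).
#' @param mcmc an [mcmc_config()] object.
#' @return object of class `stimtype_fit`: `summary` with per-condition
#'   posterior predicted means and 89\% CrIs, `draws` (matrix with one column
#'   per condition mean), `diagnostics`, `converged`.
#' @export
fit_stimtype_glmm <- function(table, mcmc = mcmc_config()) {
  stopifnot(inherits(mcmc, "mcmc_config"),
            all(c("subject", "stimulus_type", "filter", "norm_dprime")
                %in% names(table)))
  tab <- table[!(table$filter %in% c("fullspectrum", "180")), ]
  types <- c("natural", "inverted", "negated")
  if (!all(types %in% tab$stimulus_type))
    stop("all three stimulus types required", call. = FALSE)
  avg <- stats::aggregate(norm_dprime ~ subject + stimulus_type, data = tab,
                          FUN = mean)
  subjects <- sort(unique(avg$subject))
  avg$sidx <- match(avg$subject, subjects)
  avg$tidx <- match(avg$stimulus_type, types)

  model_string <- "
model {
  for (i in 1:N) {
    mu[i] <- b[t[i]] + xi[1] * ur[s[i], 1] +
             (t[i] == 2) * xi[2] * ur[s[i], 2] +
             (t[i] == 3) * xi[3] * ur[s[i], 3]
    y[i] ~ dnorm(mu[i], tau_res)
  }
  for (k in 1:3) { b[k] ~ dnorm(0, 1.0E-4) }
  for (j in 1:J) { ur[j, 1:3] ~ dmnorm(zero3, Omega) }
  Omega ~ dwish(I3, 4)
  for (k in 1:3) { xi[k] ~ dt(0, 0.16, 3) T(0,) }
  tau_res <- pow(sigma_res, -2)
  sigma_res ~ dt(0, 0.16, 3) T(0,)
}"
  # b[k] is the population mean of condition k directly (cell-means coding);
  # treatment-coded intercept/slopes are recoverable as b[1], b[k]-b[1].
  data <- list(N = nrow(avg), J = length(subjects), y = avg$norm_dprime,
               s = avg$sidx, t = avg$tidx, zero3 = rep(0, 3), I3 = diag(3))
  cellmeans <- stats::aggregate(norm_dprime ~ tidx, data = avg, FUN = mean)
  inits <- list(b = cellmeans$norm_dprime[order(cellmeans$tidx)],
                sigma_res = stats::sd(avg$norm_dprime), xi = rep(0.5, 3))
  draws <- .run_jags(model_string, data, monitor = c("b", "xi", "sigma_res"),
                     mcmc = mcmc, inits = inits)
  mat <- as.matrix(draws)
  cond <- mat[, sprintf("b[%d]", 1:3)]
  colnames(cond) <- types

  summ <- do.call(rbind, lapply(types, function(ty) {
    ci <- credible_interval(cond[, ty], 0.89)
    data.frame(stimulus_type = ty, mean = mean(cond[, ty]),
               median = stats::median(cond[, ty]),
               cri_lower = ci[1], cri_upper = ci[2])
  }))

  diag_df <- .diagnose(draws[, c(sprintf("b[%d]", 1:3), "sigma_res"),
                             drop = FALSE])
  diag_df$divergences <- NA_integer_
  converged <- all(is.finite(diag_df$rhat)) && all(diag_df$rhat < 1.01)
  if (!converged)
    warning("stimulus-type GLMM: Rhat > 1.01; inspect $diagnostics",
            call. = FALSE)
  structure(list(summary = summ, draws = cond, diagnostics = diag_df,
                 converged = converged, mcmc = mcmc, data = avg),
            class = "stimtype_fit")
}

#' @export
print.stimtype_fit <- function(x, ...) {
  cat("Bayesian stimulus-type GLMM (predicted condition means, 89% CrI)\n")
  s <- x$summary
  s[, -1] <- round(s[, -1], 3)
  print(s, row.names = FALSE)
  invisible(x)
}
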