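#' Correlate subject-level tuning parameters across effect types
#'
#' For each of the four Gaussian parameters, the Pearson correlation between
#' the subject-level posterior-mean estimates for the inversion effect and
#' those for the negation effect, with a two-sided t-test p-value and a 95\%
#' Fisher-z confidence interval. High correlations indicate that the two
#' manipulations disrupt recognition through functionally linked tuning.
#'
#' @param fit a [fit_tuning_model()] result (its `$subject` table).
#' @return data frame with one row per parameter: `r`, `p_value`,
#'   `ci_lower`, `ci_upper`, `n`.
#' @export
subject_parameter_correlations <- function(fit) {
  stopifnot(inherits(fit, "tuning_fit"))
  sub <- fit$subject
  out <- lapply(unique(sub$parameter), function(par) {
    x <- sub$estimate[sub$parameter == par & sub$effect_type == "inversion"]
    y <- sub$estimate[sub$parameter == par & sub$effect_type == "negation"]
    if (length(x) < 3L) stop("need at least 3 subjects", call. = FALSE)
    ct <- stats::cor.test(x, y)
    data.frame(parameter = par, r = unname(ct$estimate),
               p_value = ct$p.value,
               ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
               n = length(x))
  })
  do.call(rbind, out)
}

#' First-order partial correlation
#'
#' Pearson correlation between `x` and `y` after removing the variance each
#' shares with `control` (residualization; equal to the closed form
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`). Used to check
#' that cross-effect parameter correlations are not driven by the shared
#' natural-condition baseline. The t-test uses n - 3 degrees of freedom and
#' the Fisher-z interval the matching effective sample size.
#'
#' @param x,y,control equal-length numeric vectors, n >= 4.
#' @param conf_level confidence level for the Fisher-z interval.
#' @return data frame row: `r`, `p_value`, `ci_lower`, `ci_upper`, `n`.
#' @export
partial_correlation <- function(x, y, control, conf_level = 0.95) {
  n <- length(x)
  stopifnot(length(y) == n, length(control) == n)
  if (n < 4L) stop("need at least 4 observations", call. = FALSE)
  if (stats::sd(control) < 1e-12) {
    warning("control has zero variance; returning plain correlation",
            call. = FALSE)
    ct <- stats::cor.test(x, y, conf.level = conf_level)
    return(data.frame(r = unname(ct$estimate), p_value = ct$p.value,
                      ci_lower = ct$conf.int[1], ci_upper = ct$conf.int[2],
                      n = n))
  }
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, control)
  ryz <- stats::cor(y, control)
  denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
  # a variable collinear with the control has no residual variance left;
  # by convention the partial correlation is then 0
  r <- if (denom < 1e-12) 0 else (rxy - rxz * ryz) / denom
  df <- n - 3L
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  z <- atanh(r)
  se <- 1 / sqrt(n - 4L)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(r = r, p_value = p,
             ci_lower = tanh(z - q * se), ci_upper = tanh(z + q * se),
             n = n)
}

#' Partial correlations of tuning parameters controlling for the natural
#' condition
#'
#' Re-runs [subject_parameter_correlations()] as partial correlations, per
#' Gaussian parameter, controlling for each subject's mean natural-condition
#' normalized sensitivity.
#'
#' @param fit a [fit_tuning_model()] result.
#' @param sensitivity normalized sensitivity table (source of the
#'   natural-condition control variable).
#' @export
partial_parameter_correlations <- function(fit, sensitivity) {
  stopifnot(inherits(fit, "tuning_fit"))
  nat <- sensitivity[sensitivity$stimulus_type == "natural" &
                       !(sensitivity$filter %in% c("fullspectrum", "180")), ]
  ctrl <- stats::aggregate(norm_dprime ~ subject, data = nat, FUN = mean)
  sub <- fit$subject
  subjects <- sort(unique(sub$subject))
  ctrl <- ctrl$norm_dprime[match(subjects, ctrl$subject)]
  out <- lapply(unique(sub$parameter), function(par) {
    x <- sub$estimate[sub$parameter == par & sub$effect_type == "inversion"]
    y <- sub$estimate[sub$parameter == par & sub$effect_type == "negation"]
    cbind(parameter = par, partial_correlation(x, y, ctrl))
  })
  do.call(rbind, out)
}
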