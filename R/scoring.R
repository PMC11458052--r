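#' Flag response-time outliers
#'
#' Per subject, flags as excluded every trial whose RT falls outside
#' mean +/- 2.5 sd, with mean and sd computed once (single pass, not
#' iterated) over that subject's trials. If a subject's RTs have zero
#' variance nothing is flagged.
#'
#' @param trials trial data frame with `subject` and `rt` columns.
#' @return the trials with a logical `excluded` column.
#' @export
filter_rt_outliers <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("subject", "rt") %in% names(trials)))
  if (any(trials$rt <= 0)) stop("response times must be positive", call. = FALSE)
  excluded <- logical(nrow(trials))
  for (s in unique(trials$subject)) {
    i <- trials$subject == s
    if (sum(i) < 2L) stop("every subject needs at least 2 trials", call. = FALSE)
    m <- mean(trials$rt[i]); sd_ <- stats::sd(trials$rt[i])
    if (sd_ > 0)
      excluded[i] <- trials$rt[i] < m - 2.5 * sd_ | trials$rt[i] > m + 2.5 * sd_
  }
  trials$excluded <- excluded
  trials
}

#' Log-linear corrected d-prime
#'
#' Sensitivity for a same/different condition cell, with a *same* response on
#' a same-identity pair counted as a hit and a *same* response on a
#' different-identity pair as a false alarm. The log-linear correction adds
#' 0.5 to the hit and false-alarm counts and 1 to the trial totals, keeping
#' d-prime finite at floor and ceiling rates:
#' `qnorm((hits + 0.5)/(n_same + 1)) - qnorm((fa + 0.5)/(n_diff + 1))`.
#'
#' @param hits,false_alarms counts.
#' @param n_same,n_diff trial totals (> 0).
#' @param correction `"loglinear"` (counts + 0.5, totals + 1; default) or
#'   `"counts_only"` (+0.5 to counts, totals unchanged).
#' @return finite d-prime; positive values mean better-than-chance
#'   discrimination of *same*.
#' @export
loglinear_dprime <- function(hits, false_alarms, n_same, n_diff,
                             correction = c("loglinear", "counts_only")) {
  correction <- match.arg(correction)
  if (any(n_same <= 0) || any(n_diff <= 0))
    stop("trial counts must be positive", call. = FALSE)
  if (any(hits < 0 | hits > n_same) || any(false_alarms < 0 | false_alarms > n_diff))
    stop("counts out of range", call. = FALSE)
  denom_s <- if (correction == "loglinear") n_same + 1 else n_same
  denom_d <- if (correction == "loglinear") n_diff + 1 else n_diff
  stats::qnorm((hits + 0.5) / denom_s) -
    stats::qnorm((false_alarms + 0.5) / denom_d)
}

#' Per-condition sensitivity table
#'
#' Aggregates non-excluded trials into hit / false-alarm counts per subject x
#' stimulus type x orientation filter and computes the log-linear corrected
#' d-prime for each cell.
#'
#' @param trials trial data frame with `subject`, `stimulus_type`, `filter`,
#'   `is_same`, `response_same`, and optionally `excluded`.
#' @inheritParams loglinear_dprime
#' @return data frame with one row per cell: counts plus `dprime`.
#' @export
sensitivity_table <- function(trials, correction = "loglinear") {
  need <- c("subject", "stimulus_type", "filter", "is_same", "response_same")
  stopifnot(all(need %in% names(trials)))
  if (!is.null(trials$excluded)) trials <- trials[!trials$excluded, ]
  agg <- stats::aggregate(
    cbind(n_same = is_same, hits = is_same & response_same,
          n_diff = !is_same, false_alarms = !is_same & response_same) ~
      subject + stimulus_type + filter,
    data = trials, FUN = sum)
  agg$dprime <- loglinear_dprime(agg$hits, agg$false_alarms,
                                 agg$n_same, agg$n_diff,
                                 correction = correction)
  agg[order(agg$subject, agg$stimulus_type, agg$filter), ]
}

#' Z-normalize sensitivity
#'
#' Adds `norm_dprime`, the z-transformed d-prime used as the modelled
#' response variable. By default (`scope = "grand"`) the mean and sd are
#' taken over *all* subject x condition cells, so condition differences are
#' preserved while the grand mean becomes 0 and the grand sd 1;
#' `scope = "subject"` standardizes within each subject instead.
#'
#' @param table a [sensitivity_table()].
#' @param scope `"grand"` or `"subject"`.
#' @export
normalize_sensitivity <- function(table, scope = c("grand", "subject")) {
  scope <- match.arg(scope)
  stopifnot("dprime" %in% names(table))
  if (nrow(table) < 2L) stop("need at least 2 cells", call. = FALSE)
  z <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s < 1e-12)
      stop("degenerate data: zero d-prime variance", call. = FALSE)
    (x - mean(x)) / s
  }
  table$norm_dprime <-
    if (scope == "grand") z(table$dprime)
    else stats::ave(table$dprime, table$subject, FUN = z)
  table
}

#' Duplicate 0-degree performance at 180 degrees
#'
#' Orientation is circular with period 180, so the 0-degree cells are copied
#' to 180 degrees, giving the filter grid 0, 30, ..., 180 used by the tuning
#' model (the duplicated point enters the likelihood twice, exactly as the
#' curve was fit). Idempotent; full-spectrum cells are untouched.
#'
#' @param table a sensitivity (or effect) data frame with a `filter` column.
#' @export
duplicate_circular <- function(table) {
  stopifnot("filter" %in% names(table))
  if (!any(table$filter == "0"))
    stop("no 0-degree entries to duplicate", call. = FALSE)
  out <- table[table$filter != "180", ]
  dup <- out[out$filter == "0", ]
  dup$filter <- "180"
  rbind(out, dup)
}

#' Inversion and negation effect curves
#'
#' Per subject and orientation filter, the inversion effect is
#' normd'(natural) - normd'(inverted) and the negation effect
#' normd'(natural) - normd'(negated). Full-spectrum cells are excluded: the
#' tuning model is about orientation.
#'
#' @param table a normalized sensitivity table (after
#'   [normalize_sensitivity()] and [duplicate_circular()]).
#' @return data frame `subject`, `filter_deg`, `inversion_effect`,
#'   `negation_effect`.
#' @export
compute_effects <- function(table) {
  stopifnot(all(c("subject", "stimulus_type", "filter", "norm_dprime")
                %in% names(table)))
  tab <- table[table$filter != "fullspectrum", ]
  wide <- stats::reshape(
    tab[, c("subject", "stimulus_type", "filter", "norm_dprime")],
    idvar = c("subject", "filter"), timevar = "stimulus_type",
    direction = "wide")
  names(wide) <- sub("^norm_dprime\\.", "", names(wide))
  if (!all(c("natural", "inverted", "negated") %in% names(wide)) ||
      anyNA(wide[, c("natural", "inverted", "negated")]))
    stop("all three stimulus types required per subject x filter",
         call. = FALSE)
  out <- data.frame(subject = wide$subject,
                    filter_deg = as.numeric(wide$filter),
                    inversion_effect = wide$natural - wide$inverted,
                    negation_effect = wide$natural - wide$negated)
  out[order(out$subject, out$filter_deg), ]
}

#' Score a cohort of trials
#'
#' Full scoring pipeline: RT outlier exclusion, per-cell log-linear d-prime,
#' grand z-normalization, circular duplication of the 0-degree cells, and
#' effect-curve computation.
#'
#' @param trials trial data frame (e.g. from [simulate_cohort()]).
#' @inheritParams normalize_sensitivity
#' @return list with `sensitivity` (normalized, duplicated table) and
#'   `effects` (effect curves).
#' @export
score_trials <- function(trials, scope = "grand") {
  trials <- filter_rt_outliers(trials)
  tab <- sensitivity_table(trials)
  tab <- normalize_sensitivity(tab, scope = scope)
  tab <- duplicate_circular(tab)
  list(sensitivity = tab, effects = compute_effects(tab))
}
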