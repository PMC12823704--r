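# Synthetic distribution of 10-year combined-endpoint risk.
#
# Risk per (sex, age) is modelled log-normally: the median rises
# exponentially with age (log-linear) and saturates above `sat_age`; the
# log-scale spread is constant. The distribution is upper-truncated at 1 by
# mapping mass above 1 to a point mass at 1, which keeps tail probabilities
# and conditional means in closed form. This is a stand-in for applying a
# risk equation to a national risk-factor survey, which the pipeline treats
# as an input.

#' Construct a synthetic 10-year risk distribution
#'
#' @param median_ref Named numeric, the median 10-year risk at `ref_age` per
#'   sex. Defaults place a 40-year-old man's median near 5%.
#' @param log_slope Increase of log-median risk per year of age.
#' @param ref_age Reference age for `median_ref`.
#' @param sat_age Age above which the median stops rising.
#' @param sdlog Log-scale standard deviation (0 gives a degenerate,
#'   single-point risk per age).
#' @return An object of class `risk_distribution`.
#' @export
risk_distribution <- function(median_ref = c(female = 0.028, male = 0.040),
                              log_slope = 0.028, ref_age = 40, sat_age = 85,
                              sdlog = 0.35) {
  if (!all(SEXES %in% names(median_ref)) || any(median_ref <= 0) ||
      any(median_ref >= 1))
    stop("`median_ref` must be in (0,1) and named for both sexes", call. = FALSE)
  if (sdlog < 0 || log_slope < 0)
    stop("`sdlog` and `log_slope` must be >= 0", call. = FALSE)
  structure(list(median_ref = median_ref[SEXES], log_slope = log_slope,
                 ref_age = ref_age, sat_age = sat_age, sdlog = sdlog),
            class = "risk_distribution")
}

mu_log <- function(dist, sex, ages) {
  log(dist$median_ref[[sex]]) +
    dist$log_slope * (pmin(ages, dist$sat_age) - dist$ref_age)
}

#' Tail probability and conditional mean of the risk distribution
#'
#' Closed-form `P(risk > threshold)` and `E[risk | risk > threshold]` per
#' age for one sex, with the upper truncation at 1 respected.
#'
#' @param dist A [risk_distribution()].
#' @param sex `"female"` or `"male"`.
#' @param ages Integer ages.
#' @param threshold Risk threshold in (0, 1).
#' @return A list of numeric vectors `p_above` and `mean_above`
#'   (`mean_above` is `NA` where `p_above` is 0).
#' @export
risk_tail <- function(dist, sex, ages, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  sex <- match.arg(sex, SEXES)
  mu <- mu_log(dist, sex, ages)
  s <- dist$sdlog
  if (s == 0) {
    med <- pmin(exp(mu), 1)
    p <- as.numeric(med > threshold)
    return(list(p_above = p, mean_above = ifelse(p > 0, med, NA_real_)))
  }
  z_t <- (log(threshold) - mu) / s
  z_1 <- (0 - mu) / s
  p_above <- stats::pnorm(z_t, lower.tail = FALSE)
  # E[min(X,1) 1{X > t}] = e^{mu + s^2/2} (Phi(s - z_t) - Phi(s - z_1)) + P(X >= 1)
  partial <- exp(mu + s^2 / 2) *
    (stats::pnorm(s - z_t) - stats::pnorm(s - z_1)) +
    stats::pnorm(z_1, lower.tail = FALSE)
  mean_above <- ifelse(p_above > 0, partial / p_above, NA_real_)
  list(p_above = p_above, mean_above = pmin(mean_above, 1))
}

#' Treated population share and mean risk above a threshold
#'
#' The share of the total (ages 25-99) population at or above `min_age`
#' whose 10-year risk exceeds `threshold`, and the population-weighted mean
#' risk among those treated.
#'
#' @param dist A [risk_distribution()].
#' @param threshold Risk threshold in (0, 1).
#' @param min_age Minimum treatment age.
#' @param pop A `population_structure`.
#' @return A list with `share` (fraction of the total 25-99 population),
#'   `mean_risk` (`NA` if no one qualifies), and `treated_persons`.
#' @export
treated_share_and_mean <- function(dist, threshold, min_age, pop) {
  pop <- validate_population(pop)
  total <- sum(pop$persons)
  ages <- min_age:AGE_MAX
  treated <- 0; risk_sum <- 0
  for (sx in SEXES) {
    tl <- risk_tail(dist, sx, ages, threshold)
    w <- pop_lookup(pop, sx, ages) * tl$p_above
    treated <- treated + sum(w)
    risk_sum <- risk_sum + sum(w * ifelse(is.na(tl$mean_above), 0, tl$mean_above))
  }
  list(share = treated / total,
       mean_risk = if (treated > 0) risk_sum / treated else NA_real_,
       treated_persons = treated)
}

#' Annual budget impact of statin therapy
#'
#' Undiscounted steady-state annual payer cost: treated share times the
#' population basis times the annual statin cost.
#'
#' @param share Treated share (fraction of `population_total`).
#' @param population_total Persons in the population basis the share refers
#'   to.
#' @param statin_annual Euros per treated person per year.
#' @return Euros per year.
#' @export
budget_impact <- function(share, population_total, statin_annual = 100) {
  stopifnot(share >= 0, share <= 1, population_total >= 0, statin_annual >= 0)
  share * population_total * statin_annual
}

#' Population-level life-expectancy gains
#'
#' Aggregates per-age life-expectancy gains of persons entering treatment at
#' each age at or above `start_age` into (i) the mean gain of the treated
#' population (weights: persons above threshold per age and sex) and
#' (ii) the mean gain across the whole 25-99 population, where the
#' untreated contribute zero.
#'
#' @param gains Data frame with columns `sex`, `age`, `gain` covering ages
#'   `start_age` to 99 for both sexes.
#' @param dist A [risk_distribution()].
#' @param threshold Risk threshold.
#' @param pop A `population_structure`.
#' @param start_age Minimum treatment age.
#' @return A list with `treated` (`NA` when no one qualifies) and `total`.
#' @export
population_le_gain <- function(gains, dist, threshold, pop, start_age) {
  pop <- validate_population(pop)
  ages <- start_age:AGE_MAX
  wsum <- 0; gsum <- 0
  for (sx in SEXES) {
    g <- gains$gain[gains$sex == sx][match(ages, gains$age[gains$sex == sx])]
    if (any(is.na(g)))
      stop(sprintf("`gains` must cover ages %d-%d for sex '%s'",
                   start_age, AGE_MAX, sx), call. = FALSE)
    tl <- risk_tail(dist, sx, ages, threshold)
    w <- pop_lookup(pop, sx, ages) * tl$p_above
    wsum <- wsum + sum(w)
    gsum <- gsum + sum(w * g)
  }
  share_total <- wsum / sum(pop$persons)
  treated <- if (wsum > 0) gsum / wsum else NA_real_
  list(treated = treated,
       total = if (wsum > 0) treated * share_total else 0)
}
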