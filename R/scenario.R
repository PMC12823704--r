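# Scenario evaluation: one (threshold, start age) cell and the full grid.
#
# A cell is evaluated per sex — calibrate the cardiovascular event rates so
# the untreated 10-year combined-endpoint risk at the start age equals the
# cell's target, run treated and untreated cohorts, value them — and then
# averaged across the sexes with the population's sex proportions at the
# start age. By default the calibration target is the mean risk of the
# treated stratum (everyone above the threshold), because a population row
# treats the whole stratum, not marginal persons at the threshold;
# `calibrate_to = "threshold"` gives the point-risk alternative.

cell_outcomes <- function(rates, sex, start_age, target, mult, effect,
                          weights, costs) {
  cal <- calibrate_risk(rates, sex, start_age, target, mult)
  untx <- run_cohort(cal$rates, sex, start_age, treated = FALSE,
                     effect = effect, mult = mult)
  tx <- run_cohort(cal$rates, sex, start_age, treated = TRUE,
                   effect = effect, mult = mult)
  r <- costs$discount_rate
  list(k = cal$k, untx = untx, tx = tx,
       qaly_untx = qalys(untx, weights, r), qaly_tx = qalys(tx, weights, r),
       le_untx = life_expectancy(untx), le_tx = life_expectancy(tx),
       statin = statin_cost(tx, costs),
       avoided = event_costs(untx, costs) - event_costs(tx, costs),
       arr5 = {
         h <- min(5L, length(untx$ages))
         untx$cum_first_event[h] - tx$cum_first_event[h]
       })
}

# per-age life-expectancy gains of a person entering treatment at each age,
# calibrated to the age's own conditional mean risk above the threshold
le_gains_by_age <- function(rates, sex, threshold, dist, mult, effect) {
  tl <- risk_tail(dist, sex, AGES, threshold)
  gain <- numeric(length(AGES))
  for (i in seq_along(AGES)) {
    if (tl$p_above[i] <= 0) next  # zero weight in the aggregation
    target <- min(tl$mean_above[i], 0.99)
    cal <- calibrate_risk(rates, sex, AGES[i], target, mult)
    untx <- run_cohort(cal$rates, sex, AGES[i], treated = FALSE,
                       effect = effect, mult = mult)
    tx <- run_cohort(cal$rates, sex, AGES[i], treated = TRUE,
                     effect = effect, mult = mult)
    gain[i] <- life_expectancy(tx) - life_expectancy(untx)
  }
  data.frame(sex = sex, age = AGES, gain = gain)
}

#' Evaluate one cost-effectiveness scenario cell
#'
#' Calibrates, runs and values the cohort model for one risk threshold and
#' treatment start age, cross-sex averaged: 5-year NNT, discounted QALYs
#' gained, ICER, avoided event costs, treated population share and mean
#' risk, annual budget impact, and life-expectancy gains of the treated and
#' total population.
#'
#' @param threshold 10-year combined-endpoint risk threshold in (0, 1).
#' @param start_age Treatment start age (25-99).
#' @param lt A `life_table` (default synthetic).
#' @param pop A `population_structure` (default synthetic from `lt`).
#' @param dist A [risk_distribution()] describing per-age 10-year risks.
#' @param calibrate_to `"mean_risk"` (default) calibrates the cohort to the
#'   mean risk of the treated stratum; `"threshold"` to the threshold
#'   itself.
#' @param target_risk Optional explicit calibration target overriding both
#'   modes (used with externally supplied stratum means).
#' @param share Optional externally supplied treated share (fraction of the
#'   total population) overriding the risk-distribution computation.
#' @param ratios,mult,effect,weights,costs Model parameter objects; defaults
#'   are the published values.
#' @param population_total Population basis for the budget (default: total
#'   persons in `pop`).
#' @param le_gain Compute population life-expectancy gains (involves
#'   per-age calibration over all ages above `start_age`; default `TRUE`).
#' @param sim Optional [sim_config()]; when supplied, a paired
#'   microsimulation provides 95% CIs for the QALY gain.
#' @return An object of class `cea_scenario`.
#' @export
cea_scenario <- function(threshold, start_age,
                         lt = synthetic_life_table(),
                         pop = synthetic_population(lt),
                         dist = risk_distribution(),
                         calibrate_to = c("mean_risk", "threshold"),
                         target_risk = NULL, share = NULL,
                         ratios = ratio_config(),
                         mult = history_multipliers(),
                         effect = treatment_effect(),
                         weights = utility_weights(),
                         costs = cost_params(),
                         population_total = NULL,
                         le_gain = TRUE, sim = NULL) {
  stopifnot(threshold > 0, threshold < 1,
            start_age >= AGE_MIN, start_age <= AGE_MAX)
  calibrate_to <- match.arg(calibrate_to)
  lt <- validate_life_table(lt)
  pop <- validate_population(pop)
  rates <- derive_event_rates(lt, ratios)

  sm <- treated_share_and_mean(dist, threshold, start_age, pop)
  if (!is.null(share)) sm$share <- share
  if (is.null(target_risk))
    target_risk <- switch(calibrate_to,
                          mean_risk = sm$mean_risk,
                          threshold = threshold)
  if (!is.finite(target_risk))
    stop("no one above the threshold: calibration target undefined",
         call. = FALSE)

  per_sex <- lapply(stats::setNames(SEXES, SEXES), function(sx)
    cell_outcomes(rates, sx, start_age, target_risk, mult, effect,
                  weights, costs))
  sw <- sex_proportions(pop, start_age)[, 1]
  avg <- function(field)
    sum(vapply(SEXES, function(sx) per_sex[[sx]][[field]], numeric(1)) * sw[SEXES])

  qaly_gain <- avg("qaly_tx") - avg("qaly_untx")
  le_gain_ind <- avg("le_tx") - avg("le_untx")
  statin <- avg("statin")
  avoided <- avg("avoided")
  arr5 <- avg("arr5")
  nnt5 <- if (arr5 > 0) 1 / arr5 else Inf
  icer_val <- if (qaly_gain > 0) statin / qaly_gain else NA_real_

  if (is.null(population_total)) population_total <- sum(pop$persons)
  budget <- budget_impact(sm$share, population_total, costs$statin_annual)

  le_pop <- list(treated = NA_real_, total = NA_real_)
  if (le_gain) {
    gains <- do.call(rbind, lapply(SEXES, function(sx)
      le_gains_by_age(rates, sx, threshold, dist, mult, effect)))
    le_pop <- population_le_gain(gains, dist, threshold, pop, start_age)
  }

  res <- structure(list(
    threshold = threshold, start_age = start_age,
    target_risk = target_risk, calibrate_to = calibrate_to,
    k = vapply(SEXES, function(sx) per_sex[[sx]]$k, numeric(1)),
    nnt_5y = nnt5, qaly_gain = qaly_gain, qaly_ci = c(NA_real_, NA_real_),
    icer = icer_val, statin_cost = statin, avoided_event_costs = avoided,
    share = sm$share, mean_risk_treated = sm$mean_risk,
    budget = budget, le_gain_individual = le_gain_ind,
    le_gain_treated_pop = le_pop$treated, le_gain_total_pop = le_pop$total,
    sex_weights = sw, per_sex = per_sex,
    params = list(ratios = ratios, mult = mult, effect = effect,
                  weights = weights, costs = costs),
    rates = rates, pop = pop, dist = dist
  ), class = "cea_scenario")

  if (!is.null(sim)) {
    ci <- simulate(res, sim = sim)
    res$qaly_ci <- ci$qaly_gain$ci
    res$microsim <- ci
  }
  res
}

#' Microsimulation confidence intervals for a scenario
#'
#' Runs the paired treated/untreated microsimulation for each sex with the
#' scenario's calibrated rates and returns cross-sex-averaged means and
#' percentile-bootstrap 95% CIs. Per-iteration outcomes of the two sexes are
#' combined with the scenario's sex weights before the bootstrap, so the
#' interval refers to the cross-sex average reported in the tables.
#'
#' @param object A `cea_scenario`.
#' @param nsim,seed Unused standard [stats::simulate()] arguments; control
#'   the run via `sim`.
#' @param sim A [sim_config()].
#' @param ... Ignored.
#' @return A list with `qaly_gain`, `le_gain`, `statin_cost`,
#'   `avoided_event_cost`, each holding `mean` and `ci`, plus the per-sex
#'   microsimulation outputs.
#' @export
simulate.cea_scenario <- function(object, nsim = 1, seed = NULL,
                                  sim = sim_config(), ...) {
  p <- object$params
  per_sex <- lapply(stats::setNames(SEXES, SEXES), function(sx) {
    cal <- calibrate_risk(object$rates, sx, object$start_age,
                          object$target_risk, p$mult)
    cfg <- sim
    cfg$seed <- sim$seed + match(sx, SEXES)
    microsim_outcomes(cal$rates, sex = sx, start_age = object$start_age,
                      config = cfg, weights = p$weights, costs = p$costs,
                      effect = p$effect, mult = p$mult)
  })
  sw <- object$sex_weights
  mix <- function(f) {
    x <- sw[["female"]] * f(per_sex$female) + sw[["male"]] * f(per_sex$male)
    list(mean = mean(x), ci = boot_ci_mean(x))
  }
  set.seed(sim$seed + 97L)
  out <- list(
    qaly_gain = mix(function(s) s$treated$qaly - s$untreated$qaly),
    le_gain = mix(function(s) s$treated$life_years - s$untreated$life_years),
    statin_cost = mix(function(s) s$treated$statin_cost),
    avoided_event_cost = mix(function(s) s$untreated$event_cost -
                               s$treated$event_cost),
    per_sex = lapply(per_sex, function(s)
      s[c("qaly_gain", "le_gain", "statin_cost", "avoided_event_cost",
          "cum10_untreated", "cum10_treated")])
  )
  out
}

#' Evaluate a grid of scenarios
#'
#' Runs [cea_scenario()] over every (threshold, start age) combination and
#' collects the results in one table, mirroring the published column order:
#' NNT, QALYs gained (with CI when `sim` is given), ICER, avoided event
#' costs, treated share, mean treated risk, annual budget, and
#' life-expectancy gains. Per-age life-expectancy gain curves are computed
#' once per threshold and shared across start ages.
#'
#' @inheritParams cea_scenario
#' @param thresholds Numeric vector of risk thresholds.
#' @param start_ages Integer vector of treatment start ages.
#' @param reference_grid Optional data frame with columns `threshold`,
#'   `start_age`, `mean_risk` and optionally `share` (fractions): externally
#'   supplied stratum summaries (e.g. published values) that override the
#'   risk-distribution computation cell by cell.
#' @param parity If `TRUE`, population life-expectancy gains for the
#'   youngest start age (25) are reported as `NA` (reason:
#'   `insufficient_database`), matching the published table's footnote.
#' @param verbose Print per-cell progress.
#' @return A `cea_grid` data frame; the full `cea_scenario` objects are
#'   attached as attribute `"scenarios"`.
#' @export
cea_grid <- function(thresholds = c(0.075, 0.10, 0.15),
                     start_ages = c(25L, 40L, 50L, 60L, 70L),
                     lt = synthetic_life_table(),
                     pop = synthetic_population(lt),
                     dist = risk_distribution(),
                     calibrate_to = "mean_risk",
                     reference_grid = NULL,
                     ratios = ratio_config(), mult = history_multipliers(),
                     effect = treatment_effect(),
                     weights = utility_weights(), costs = cost_params(),
                     population_total = NULL, le_gain = TRUE,
                     parity = FALSE, sim = NULL, verbose = FALSE) {
  lt <- validate_life_table(lt)
  pop <- validate_population(pop)
  rates <- derive_event_rates(lt, ratios)
  if (is.null(population_total)) population_total <- sum(pop$persons)

  rows <- list(); scenarios <- list()
  for (th in thresholds) {
    gains <- NULL
    if (le_gain) {
      gains <- do.call(rbind, lapply(SEXES, function(sx)
        le_gains_by_age(rates, sx, th, dist, mult, effect)))
    }
    for (a in start_ages) {
      target <- NULL; share <- NULL
      if (!is.null(reference_grid)) {
        ref <- reference_grid[abs(reference_grid$threshold - th) < 1e-9 &
                                reference_grid$start_age == a, , drop = FALSE]
        if (nrow(ref) != 1L)
          stop(sprintf("reference grid has no row for threshold %g, age %d",
                       th, a), call. = FALSE)
        target <- ref$mean_risk
        if ("share" %in% names(ref)) share <- ref$share
      }
      sc <- tryCatch(
        cea_scenario(th, a, lt = lt, pop = pop, dist = dist,
                     calibrate_to = calibrate_to, target_risk = target,
                     share = share, ratios = ratios, mult = mult,
                     effect = effect, weights = weights, costs = costs,
                     population_total = population_total,
                     le_gain = FALSE, sim = sim),
        error = function(e)
          stop(sprintf("scenario (threshold %g, start age %d): %s",
                       th, a, conditionMessage(e)), call. = FALSE))
      if (le_gain) {
        lp <- population_le_gain(gains, dist, th, pop, a)
        sc$le_gain_treated_pop <- lp$treated
        sc$le_gain_total_pop <- lp$total
      }
      if (parity && a == min(start_ages)) {
        sc$le_gain_treated_pop <- NA_real_
        sc$le_gain_total_pop <- NA_real_
        sc$le_gain_reason <- "insufficient_database"
      }
      if (verbose)
        message(sprintf("threshold %.3f, start age %d: k = %.3f/%.3f",
                        th, a, sc$k[["female"]], sc$k[["male"]]))
      scenarios[[length(scenarios) + 1L]] <- sc
      rows[[length(rows) + 1L]] <- data.frame(
        threshold_pct = 100 * th, start_age = a,
        nnt_5y = sc$nnt_5y, qaly_gain = sc$qaly_gain,
        qaly_lo = sc$qaly_ci[1], qaly_hi = sc$qaly_ci[2],
        icer_eur = sc$icer, avoided_event_costs_eur = sc$avoided_event_costs,
        share_pct = 100 * sc$share,
        mean_risk_treated_pct = 100 * (if (!is.null(target)) target
                                       else sc$mean_risk_treated),
        budget_eur_bn = sc$budget / 1e9,
        le_gain_treated = sc$le_gain_treated_pop,
        le_gain_total = sc$le_gain_total_pop)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenarios") <- scenarios
  class(out) <- c("cea_grid", "data.frame")
  out
}
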