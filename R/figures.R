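# Tidy data products behind the two standard figures: event prevalence
# among the living over time, and the age profile of the competing-risk
# ratio.

#' Prevalence-of-event-history curves
#'
#' For each (sex, threshold, start age) and both arms, the fraction of the
#' living cohort with at least one coronary or cerebrovascular event at each
#' age, for cohorts calibrated to the stratum's risk. Curves start at 0
#' (inclusion requires no prior history); the untreated curve dominates the
#' treated one pointwise.
#'
#' @inheritParams cea_scenario
#' @param thresholds,start_ages Grid to export.
#' @return A tidy data frame: `sex`, `threshold`, `start_age`, `arm`, `age`,
#'   `prevalence`.
#' @export
fig2_series <- function(thresholds = c(0.075, 0.10, 0.15),
                        start_ages = c(40L, 50L, 60L, 70L),
                        lt = synthetic_life_table(),
                        pop = synthetic_population(lt),
                        dist = risk_distribution(),
                        calibrate_to = c("mean_risk", "threshold"),
                        ratios = ratio_config(), mult = history_multipliers(),
                        effect = treatment_effect()) {
  calibrate_to <- match.arg(calibrate_to)
  rates <- derive_event_rates(validate_life_table(lt), ratios)
  out <- list()
  for (sx in SEXES) for (th in thresholds) for (a in start_ages) {
    target <- if (calibrate_to == "mean_risk") {
      treated_share_and_mean(dist, th, a, pop)$mean_risk
    } else th
    cal <- calibrate_risk(rates, sx, a, target, mult)
    for (arm in c("untreated", "treated")) {
      traj <- run_cohort(cal$rates, sx, a, treated = arm == "treated",
                         effect = effect, mult = mult)
      # include the inclusion point (no history by definition, prevalence 0):
      # row i of dist is the occupancy after i - 1 completed cycles
      d <- traj$dist
      post <- d[, "post_chd"] + d[, "post_cve"] + d[, "post_both"]
      living <- post + d[, "event_free"]
      out[[length(out) + 1L]] <- data.frame(
        sex = sx, threshold = th, start_age = a, arm = arm,
        age = a + seq_len(nrow(d)) - 1L,
        prevalence = ifelse(living > 0, post / living, NaN))
    }
  }
  do.call(rbind, out)
}

#' Competing-risk ratio curves
#'
#' Ratio of the 10-year risk of fatal coronary or cerebrovascular death to
#' the 10-year risk of other-cause death, by age and sex, for population
#' strata whose combined 10-year event risk at each age equals the stratum
#' threshold. The ratio falls steeply with age as other-cause mortality
#' overtakes cardiovascular mortality.
#'
#' @inheritParams cea_scenario
#' @param thresholds Stratum risks.
#' @param ages Ages at which to evaluate the ratio.
#' @return A tidy data frame: `sex`, `threshold`, `age`, `ratio`.
#' @export
fig3_series <- function(thresholds = c(0.075, 0.10, 0.15), ages = 30:90,
                        lt = synthetic_life_table(),
                        ratios = ratio_config(),
                        mult = history_multipliers()) {
  rates <- derive_event_rates(validate_life_table(lt), ratios)
  out <- list()
  for (sx in SEXES) for (th in thresholds) {
    ratio <- vapply(ages, function(a) {
      cal <- calibrate_risk(rates, sx, a, th, mult)
      competing_risk_ratio(cal$rates, sx, a, mult)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(sex = sx, threshold = th,
                                          age = ages, ratio = ratio)
  }
  do.call(rbind, out)
}
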