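#' Non-fatal to fatal event ratios
#'
#' Ratios used to impute non-fatal event probabilities from cause-specific
#' mortality: for every fatal coronary event, `r_chd` non-fatal coronary
#' events are assumed to occur, and likewise `r_cve` for cerebrovascular
#' events. Defaults are the values used for the German population
#' (coronary 2.89, cerebrovascular 3.31).
#'
#' @param r_chd Non-fatal : fatal ratio for coronary heart disease events.
#' @param r_cve Non-fatal : fatal ratio for cerebrovascular events.
#' @return An object of class `ratio_config`.
#' @export
ratio_config <- function(r_chd = 2.89, r_cve = 3.31) {
  if (!is.numeric(r_chd) || length(r_chd) != 1L || !is.finite(r_chd) || r_chd <= 0)
    stop("`r_chd` must be a single positive number", call. = FALSE)
  if (!is.numeric(r_cve) || length(r_cve) != 1L || !is.finite(r_cve) || r_cve <= 0)
    stop("`r_cve` must be a single positive number", call. = FALSE)
  structure(list(r_chd = r_chd, r_cve = r_cve), class = "ratio_config")
}

#' Event-history risk multipliers
#'
#' A survivor of a non-fatal event carries an elevated risk of subsequent
#' events of the same family: coronary probabilities are multiplied by `c1`
#' after a coronary event and cerebrovascular probabilities by `c2` after a
#' cerebrovascular event. The multiplier is applied once, never compounded
#' over repeat events.
#'
#' @param c1 Coronary multiplier (default 1.444).
#' @param c2 Cerebrovascular multiplier (default 2.666).
#' @return An object of class `history_multipliers`.
#' @export
history_multipliers <- function(c1 = 1.444, c2 = 2.666) {
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 < 1)
    stop("`c1` must be a single number >= 1", call. = FALSE)
  if (!is.numeric(c2) || length(c2) != 1L || !is.finite(c2) || c2 < 1)
    stop("`c2` must be a single number >= 1", call. = FALSE)
  structure(list(c1 = c1, c2 = c2), class = "history_multipliers")
}

#' Treatment effect of statin therapy
#'
#' Relative risk reduction applied multiplicatively to all four
#' cardiovascular event probabilities (fatal and non-fatal, coronary and
#' cerebrovascular) in every age and risk stratum; other-cause mortality is
#' untouched. Default 0.30.
#'
#' @param rrr Relative risk reduction in `[0, 1)`.
#' @return An object of class `treatment_effect`.
#' @export
treatment_effect <- function(rrr = 0.30) {
  if (!is.numeric(rrr) || length(rrr) != 1L || !is.finite(rrr) || rrr < 0 || rrr >= 1)
    stop("`rrr` must be a single number in [0, 1)", call. = FALSE)
  structure(list(rrr = rrr), class = "treatment_effect")
}

#' Health-state utility weights
#'
#' Per life-year utility weights for the living states, with 95% confidence
#' intervals used by the probabilistic microsimulation. Defaults: 1.0
#' event-free, 0.9648 (0.9505-0.9758) after at least one coronary event,
#' 0.8835 (0.8414-0.9108) after at least one cerebrovascular event, and
#' 0.8524 (0.7998-0.8888) after at least one of each.
#'
#' @param w_none,w_chd,w_cve,w_both Point weights in `[0, 1]`.
#' @param ci_chd,ci_cve,ci_both Length-2 numeric 95% CIs for the three
#'   post-event weights (the event-free weight is fixed at its point value).
#' @return An object of class `utility_weights`.
#' @export
utility_weights <- function(w_none = 1.0,
                            w_chd = 0.9648, ci_chd = c(0.9505, 0.9758),
                            w_cve = 0.8835, ci_cve = c(0.8414, 0.9108),
                            w_both = 0.8524, ci_both = c(0.7998, 0.8888)) {
  w <- c(w_none, w_chd, w_cve, w_both)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stop("utility weights must lie in [0, 1]", call. = FALSE)
  if (w_both > min(w_chd, w_cve) + 1e-12 || max(w_chd, w_cve) > w_none + 1e-12)
    stop("weights must satisfy w_both <= min(w_chd, w_cve) <= w_none", call. = FALSE)
  chk_ci <- function(ci, nm) {
    if (!is.numeric(ci) || length(ci) != 2L || ci[1] > ci[2])
      stop(sprintf("`%s` must be an increasing length-2 numeric CI", nm), call. = FALSE)
    ci
  }
  structure(list(
    w_none = w_none, w_chd = w_chd, w_cve = w_cve, w_both = w_both,
    ci_chd = chk_ci(ci_chd, "ci_chd"),
    ci_cve = chk_ci(ci_cve, "ci_cve"),
    ci_both = chk_ci(ci_both, "ci_both")
  ), class = "utility_weights")
}

#' Economic cost parameters
#'
#' Direct event costs (Euros, rounded as published for Germany), annual
#' statin therapy cost, and the annual discount rate applied to both costs
#' and QALYs. `recurrent_costs` controls whether repeat non-fatal events in
#' the same person accrue the event cost each time (default) or only the
#' first time.
#'
#' @param cost_chd_fatal,cost_chd_nonfatal,cost_cve_fatal,cost_cve_nonfatal
#'   Direct event costs in Euros.
#' @param statin_annual Annual statin cost in Euros per treated person.
#' @param discount_rate Annual discount rate in `[0, 1)`; default 0.03.
#' @param recurrent_costs Logical; accrue costs for recurrent non-fatal
#'   events (default `TRUE`).
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(cost_chd_fatal = 10671, cost_chd_nonfatal = 20215,
                        cost_cve_fatal = 11874, cost_cve_nonfatal = 24044,
                        statin_annual = 100, discount_rate = 0.03,
                        recurrent_costs = TRUE) {
  costs <- c(cost_chd_fatal, cost_chd_nonfatal, cost_cve_fatal,
             cost_cve_nonfatal, statin_annual)
  if (any(!is.finite(costs)) || any(costs < 0))
    stop("all costs must be finite and >= 0", call. = FALSE)
  if (!is.finite(discount_rate) || discount_rate < 0 || discount_rate >= 1)
    stop("`discount_rate` must lie in [0, 1)", call. = FALSE)
  structure(list(
    cost_chd_fatal = cost_chd_fatal, cost_chd_nonfatal = cost_chd_nonfatal,
    cost_cve_fatal = cost_cve_fatal, cost_cve_nonfatal = cost_cve_nonfatal,
    statin_annual = statin_annual, discount_rate = discount_rate,
    recurrent_costs = isTRUE(recurrent_costs)
  ), class = "cost_params")
}

#' Microsimulation configuration
#'
#' @param n_iterations Number of sampled individual life courses per arm
#'   (default 20000).
#' @param seed Integer random seed.
#' @param sample_utilities Logical; draw utility weights per iteration from
#'   their 95% CIs (normal on the weight scale, sd = CI width / 3.92,
#'   truncated to `[0, 1]`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_iterations = 20000L, seed = 1L, sample_utilities = TRUE) {
  n_iterations <- as.integer(n_iterations)
  if (is.na(n_iterations) || n_iterations < 1L)
    stop("`n_iterations` must be >= 1", call. = FALSE)
  structure(list(n_iterations = n_iterations, seed = as.integer(seed),
                 sample_utilities = isTRUE(sample_utilities)),
            class = "sim_config")
}

#' @importFrom stats simulate
NULL

# shared age grid: integer ages 25-99, age 99 is the last modelled cycle
AGE_MIN <- 25L
AGE_MAX <- 99L
AGES <- AGE_MIN:AGE_MAX
SEXES <- c("female", "male")
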