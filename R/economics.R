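# Economic valuation of cohort trajectories.
#
# Conventions: cycles are credited at end of cycle — a person dying within a
# cycle accrues no QALY or statin cost for it, but the fatal event's direct
# cost is accrued in that cycle. Discounting starts at treatment start
# (t = 0 for the first cycle). QALYs and costs are discounted; life
# expectancy is undiscounted.

#' Discount factor
#'
#' `(1 + rate)^(-t)` with `t = 0` for the first cycle after treatment start.
#'
#' @param t Integer years from treatment start (0-based).
#' @param rate Annual discount rate.
#' @return Numeric vector of discount factors.
#' @export
discount_factor <- function(t, rate = 0.03) {
  stopifnot(all(t >= 0), rate >= 0, rate < 1)
  (1 + rate)^(-t)
}

traj_disc <- function(traj, rate) {
  discount_factor(seq_along(traj$ages) - 1L, rate)
}

# end-of-cycle occupancy rows (drops the initial distribution)
eoc <- function(traj) traj$dist[-1L, , drop = FALSE]

#' Discounted quality-adjusted life years
#'
#' Sum over cycles of the discount factor times occupancy-weighted utility
#' of the living states.
#'
#' @param traj A `cohort_trajectory`.
#' @param weights A [utility_weights()].
#' @param rate Annual discount rate.
#' @return Discounted QALYs per person at start.
#' @export
qalys <- function(traj, weights = utility_weights(), rate = 0.03) {
  w <- c(event_free = weights$w_none, post_chd = weights$w_chd,
         post_cve = weights$w_cve, post_both = weights$w_both)
  occ <- eoc(traj)[, LIVING, drop = FALSE]
  sum(traj_disc(traj, rate) * (occ %*% w))
}

#' Undiscounted life expectancy from treatment start
#'
#' Expected life-years: the sum over cycles of the living fraction at cycle
#' end, uncapped by utility weighting and undiscounted.
#'
#' @param traj A `cohort_trajectory`.
#' @return Expected life-years per person at start.
#' @export
life_expectancy <- function(traj) {
  sum(rowSums(eoc(traj)[, LIVING, drop = FALSE]))
}

#' Discounted lifelong statin cost
#'
#' Treatment is lifelong from start; the annual cost accrues for each cycle
#' a person is alive at cycle end.
#'
#' @param traj The treated arm's `cohort_trajectory`.
#' @param costs A [cost_params()].
#' @return Discounted Euros per person at start.
#' @export
statin_cost <- function(traj, costs = cost_params()) {
  living <- rowSums(eoc(traj)[, LIVING, drop = FALSE])
  sum(traj_disc(traj, costs$discount_rate) * living * costs$statin_annual)
}

#' Discounted direct event costs
#'
#' Expected incident events per cycle times unit costs, discounted. With
#' `costs$recurrent_costs = FALSE` only first non-fatal events (those
#' occurring to event-free persons) are costed.
#'
#' @param traj A `cohort_trajectory`.
#' @param costs A [cost_params()].
#' @return Discounted Euros per person at start.
#' @export
event_costs <- function(traj, costs = cost_params()) {
  ev <- traj$events
  nf <- if (costs$recurrent_costs) ev[, c("nonfatal_chd", "nonfatal_cve"), drop = FALSE]
        else traj$events_first
  percycle <- ev[, "fatal_chd"] * costs$cost_chd_fatal +
    ev[, "fatal_cve"] * costs$cost_cve_fatal +
    nf[, "nonfatal_chd"] * costs$cost_chd_nonfatal +
    nf[, "nonfatal_cve"] * costs$cost_cve_nonfatal
  sum(traj_disc(traj, costs$discount_rate) * percycle)
}

#' Incremental cost-effectiveness ratio
#'
#' Discounted statin cost of the treated arm divided by the incremental
#' discounted QALYs. By the published definition the numerator is the gross
#' statin cost; set `net = TRUE` to subtract avoided event costs.
#'
#' @param statin_cost_treated Discounted statin cost (Euros per person).
#' @param qaly_gain Incremental discounted QALYs (treated minus untreated).
#' @param avoided_event_costs Discounted avoided event costs, used only when
#'   `net = TRUE`.
#' @param net Net out avoided event costs (default `FALSE`).
#' @return Euros per QALY; `NA` with a warning when the QALY gain is not
#'   positive (ICER undefined).
#' @export
icer <- function(statin_cost_treated, qaly_gain, avoided_event_costs = 0,
                 net = FALSE) {
  if (!is.finite(qaly_gain) || qaly_gain <= 0) {
    warning("ICER undefined: QALY gain is not positive", call. = FALSE)
    return(NA_real_)
  }
  num <- statin_cost_treated - if (net) avoided_event_costs else 0
  num / qaly_gain
}

#' Five-year number needed to treat
#'
#' Inverse of the absolute reduction in the cumulative probability of a
#' first combined-endpoint event over five cycles (competing other-cause
#' mortality included in both arms).
#'
#' @param traj_treated,traj_untreated `cohort_trajectory` objects for the
#'   two arms.
#' @param horizon Horizon in cycles (default 5).
#' @return Persons needed to treat; `Inf` when the arms do not differ.
#' @export
nnt <- function(traj_treated, traj_untreated, horizon = 5L) {
  h <- min(horizon, length(traj_untreated$ages), length(traj_treated$ages))
  arr <- traj_untreated$cum_first_event[h] - traj_treated$cum_first_event[h]
  if (arr <= 0) return(Inf)
  1 / arr
}
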