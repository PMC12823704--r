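# Annual-cycle cohort engine.
#
# Seven states: four living (event-free, post-coronary, post-cerebrovascular,
# post-both) and three absorbing dead states split by cause. Within a cycle,
# the three death causes compete additively; conditional on surviving the
# cycle, non-fatal coronary and cerebrovascular events occur independently,
# so both can coincide within one year (the only route into post-both).
# Recurrent non-fatal events leave the state unchanged but are counted as
# incident events. A person who would have had a non-fatal event but dies in
# the same cycle is counted as the death only.

STATES <- c("event_free", "post_chd", "post_cve", "post_both",
            "dead_chd", "dead_cve", "dead_other")
LIVING <- STATES[1:4]
EVENT_KINDS <- c("nonfatal_chd", "nonfatal_cve", "fatal_chd", "fatal_cve",
                 "other_death")

#' One-cycle outgoing transition probabilities from a living state
#'
#' Composes the within-cycle event structure for a single person-state:
#' fatal coronary, fatal cerebrovascular and other-cause death compete
#' additively; among survivors, non-fatal coronary and cerebrovascular
#' events are independent. History multipliers are applied to `p` first via
#' [apply_history()]. The returned probabilities sum to 1.
#'
#' @param p Named per-age base probabilities (see [apply_history()]).
#' @param state A living state name.
#' @param mult A [history_multipliers()].
#' @return Named numeric over all seven states, summing to 1.
#' @export
cycle_transitions <- function(p, state, mult = history_multipliers()) {
  if (!state %in% LIVING)
    stop("`state` must be a living state", call. = FALSE)
  pe <- apply_history(p, state, mult)
  cf <- pe[["p_chd_fatal"]]; vf <- pe[["p_cve_fatal"]]
  of <- pe[["p_other_death"]]
  cn <- pe[["p_chd_nonfatal"]]; vn <- pe[["p_cve_nonfatal"]]
  if (any(c(cf, vf, of, cn, vn) < 0) || any(c(cn, vn) > 1) || cf + vf + of > 1)
    stop(sprintf("rate overflow in state '%s': effective probabilities leave [0, 1]",
                 state), call. = FALSE)
  surv <- 1 - cf - vf - of
  out <- stats::setNames(numeric(7L), STATES)
  out["dead_chd"] <- cf; out["dead_cve"] <- vf; out["dead_other"] <- of
  if (state == "event_free") {
    out["post_chd"] <- surv * cn * (1 - vn)
    out["post_cve"] <- surv * vn * (1 - cn)
    out["post_both"] <- surv * cn * vn
    out["event_free"] <- surv * (1 - cn) * (1 - vn)
  } else {
    out[state] <- surv  # recurrent non-fatal events do not change state
  }
  out
}

#' Run the deterministic cohort expectation
#'
#' Propagates the state-occupancy distribution one cycle per year of age
#' from `start_age` up to age 99 (or `n_cycles` if shorter), recording the
#' end-of-cycle distribution, expected incident events per person at start,
#' and the cumulative probability of a first combined-endpoint event.
#'
#' @param rates An `event_rates` data frame (typically calibrated).
#' @param sex `"female"` or `"male"`.
#' @param start_age First cycle's age.
#' @param treated If `TRUE`, `effect` is applied to the four CV
#'   probabilities before running.
#' @param effect A [treatment_effect()].
#' @param mult A [history_multipliers()].
#' @param n_cycles Number of one-year cycles (default: through age 99).
#' @param init Optional initial occupancy over the seven states (defaults to
#'   all mass event-free).
#' @return A `cohort_trajectory`: list with `ages`, `dist` (matrix of
#'   occupancy, one row per cycle end plus the initial row), `events`
#'   (expected incident counts per cycle for the five event kinds),
#'   `events_first` (non-fatal events occurring to event-free persons only),
#'   `first_event` (per-cycle probability of a first combined-endpoint
#'   event) and `cum_first_event`.
#' @export
run_cohort <- function(rates, sex, start_age, treated = FALSE,
                       effect = treatment_effect(), mult = history_multipliers(),
                       n_cycles = NULL, init = NULL) {
  sex <- match.arg(sex, SEXES)
  stopifnot(start_age >= AGE_MIN, start_age <= AGE_MAX)
  m <- rates_matrix(rates, sex)
  if (treated) {
    cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
    m[, cv] <- m[, cv] * (1 - effect$rrr)
  }
  max_cycles <- AGE_MAX - start_age + 1L
  n_cycles <- if (is.null(n_cycles)) max_cycles else min(n_cycles, max_cycles)
  ages <- seq.int(start_age, length.out = n_cycles)

  if (is.null(init)) {
    dist <- stats::setNames(c(1, rep(0, 6)), STATES)
  } else {
    dist <- unlist(init)[STATES]
    if (any(is.na(dist)) || any(dist < 0) || abs(sum(dist) - 1) > 1e-9)
      stop("`init` must be a distribution over the seven states", call. = FALSE)
  }

  dists <- matrix(0, nrow = n_cycles + 1L, ncol = 7L,
                  dimnames = list(NULL, STATES))
  events <- matrix(0, nrow = n_cycles, ncol = 5L,
                   dimnames = list(NULL, EVENT_KINDS))
  events_first <- matrix(0, nrow = n_cycles, ncol = 2L,
                         dimnames = list(NULL, c("nonfatal_chd", "nonfatal_cve")))
  first_event <- numeric(n_cycles)
  dists[1L, ] <- dist

  c1 <- mult$c1; c2 <- mult$c2
  for (t in seq_len(n_cycles)) {
    p <- m[as.character(ages[t]), ]
    cf <- p[["p_chd_fatal"]]; vf <- p[["p_cve_fatal"]]
    of <- p[["p_other_death"]]
    cn <- p[["p_chd_nonfatal"]]; vn <- p[["p_cve_nonfatal"]]
    eff <- rbind(  # rows: living states; cols: cf, vf, cn, vn
      event_free = c(cf, vf, cn, vn),
      post_chd   = c(c1 * cf, 0, c1 * cn, 0),
      post_cve   = c(0, c2 * vf, 0, c2 * vn),
      post_both  = c(c1 * cf, c2 * vf, c1 * cn, c2 * vn))
    occ <- dist[LIVING]
    bad <- apply(eff, 1, max) > 1 | eff[, 1] + eff[, 2] + of > 1
    if (any(bad & occ > 0))
      stop(sprintf("rate overflow at age %d (sex %s)", ages[t], sex),
           call. = FALSE)
    cfe <- eff[, 1]; vfe <- eff[, 2]; cne <- eff[, 3]; vne <- eff[, 4]
    surv <- 1 - cfe - vfe - of

    nxt <- dist
    nxt["dead_chd"] <- dist[["dead_chd"]] + sum(occ * cfe)
    nxt["dead_cve"] <- dist[["dead_cve"]] + sum(occ * vfe)
    nxt["dead_other"] <- dist[["dead_other"]] + sum(occ * of)
    ef <- occ[["event_free"]] * surv[["event_free"]]
    cn0 <- cne[["event_free"]]; vn0 <- vne[["event_free"]]
    nxt["event_free"] <- ef * (1 - cn0) * (1 - vn0)
    nxt["post_chd"] <- occ[["post_chd"]] * surv[["post_chd"]] + ef * cn0 * (1 - vn0)
    nxt["post_cve"] <- occ[["post_cve"]] * surv[["post_cve"]] + ef * vn0 * (1 - cn0)
    nxt["post_both"] <- occ[["post_both"]] * surv[["post_both"]] + ef * cn0 * vn0

    events[t, "fatal_chd"] <- sum(occ * cfe)
    events[t, "fatal_cve"] <- sum(occ * vfe)
    events[t, "other_death"] <- sum(occ * of)
    # non-fatal events are survivor-conditional; recurrent ones count too
    nf_chd <- ef * cn0 +
      occ[["post_chd"]] * surv[["post_chd"]] * cne[["post_chd"]] +
      occ[["post_both"]] * surv[["post_both"]] * cne[["post_both"]]
    nf_cve <- ef * vn0 +
      occ[["post_cve"]] * surv[["post_cve"]] * vne[["post_cve"]] +
      occ[["post_both"]] * surv[["post_both"]] * vne[["post_both"]]
    events[t, "nonfatal_chd"] <- nf_chd
    events[t, "nonfatal_cve"] <- nf_cve
    events_first[t, "nonfatal_chd"] <- ef * cn0
    events_first[t, "nonfatal_cve"] <- ef * vn0

    first_event[t] <- occ[["event_free"]] *
      (cfe[["event_free"]] + vfe[["event_free"]] +
         surv[["event_free"]] * (1 - (1 - cn0) * (1 - vn0)))

    dist <- nxt
    dists[t + 1L, ] <- dist
  }

  structure(list(
    sex = sex, start_age = start_age, treated = treated, ages = ages,
    dist = dists, events = events, events_first = events_first,
    first_event = first_event, cum_first_event = cumsum(first_event)
  ), class = "cohort_trajectory")
}

#' Prevalence of event history among the living
#'
#' Fraction of the living cohort with at least one coronary or
#' cerebrovascular event at the end of the cycle for each age.
#'
#' @param traj A `cohort_trajectory`.
#' @param age Optional single age (defaults to the whole trajectory).
#' @return Numeric vector (or scalar) of prevalence values; `NaN` when no
#'   one is alive.
#' @export
prevalence_among_living <- function(traj, age = NULL) {
  d <- traj$dist
  post <- d[, "post_chd"] + d[, "post_cve"] + d[, "post_both"]
  living <- post + d[, "event_free"]
  prev <- ifelse(living > 0, post / living, NaN)
  # row 1 is the initial distribution (start of the first cycle)
  prev_at <- stats::setNames(prev, c(traj$start_age - 1L, traj$ages))
  if (is.null(age)) return(prev_at[-1L])
  idx <- match(as.character(age), names(prev_at))
  if (any(is.na(idx))) stop("age outside trajectory", call. = FALSE)
  unname(prev[idx])
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  last <- x$dist[nrow(x$dist), ]
  cat(sprintf("Cohort trajectory: %s, start age %d, %d cycles%s\n",
              x$sex, x$start_age, length(x$ages),
              if (x$treated) " (treated)" else ""))
  cat(sprintf("  alive at end: %.4f; 10-cycle first-event risk: %.6f\n",
              sum(last[LIVING]),
              x$cum_first_event[min(10L, length(x$ages))]))
  cat(sprintf("  deaths: CHD %.4f, CVE %.4f, other %.4f\n",
              last[["dead_chd"]], last[["dead_cve"]], last[["dead_other"]]))
  invisible(x)
}
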