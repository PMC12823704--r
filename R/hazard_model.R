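# Event-rate derivation and risk calibration.
#
# The five annual event probabilities per (sex, age) are built from the
# all-cause death probability and the cause-of-death fractions:
#   p_chd_fatal  = q_all * f_chd
#   p_cve_fatal  = q_all * f_cve
#   p_other      = q_all - p_chd_fatal - p_cve_fatal
# and the non-fatal probabilities follow from fixed non-fatal:fatal ratios.
# Fatal CHD, fatal CVE and other-cause death within one cycle are mutually
# exclusive (probabilities add), matching cause-of-death bookkeeping.

RATE_COLS <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal",
               "p_cve_nonfatal", "p_other_death")

new_event_rates <- function(df) {
  df <- df[order(df$sex, df$age), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_rates", "data.frame")
  df
}

#' Derive annual event probabilities from a life table
#'
#' Splits all-cause mortality into fatal coronary, fatal cerebrovascular and
#' other-cause death using the cause-of-death fractions, then imputes
#' non-fatal event probabilities with the non-fatal:fatal ratios. The three
#' fatal probabilities sum to `q_all` exactly.
#'
#' @param lt A `life_table`.
#' @param ratios A [ratio_config()].
#' @return An `event_rates` data frame with columns `sex`, `age`,
#'   `p_chd_fatal`, `p_chd_nonfatal`, `p_cve_fatal`, `p_cve_nonfatal`,
#'   `p_other_death`.
#' @export
derive_event_rates <- function(lt, ratios = ratio_config()) {
  lt <- validate_life_table(lt)
  df <- data.frame(
    sex = lt$sex, age = lt$age,
    p_chd_fatal = lt$q_all * lt$f_chd,
    p_cve_fatal = lt$q_all * lt$f_cve
  )
  df$p_chd_nonfatal <- ratios$r_chd * df$p_chd_fatal
  df$p_cve_nonfatal <- ratios$r_cve * df$p_cve_fatal
  df$p_other_death <- lt$q_all - df$p_chd_fatal - df$p_cve_fatal
  over <- df$p_chd_nonfatal > 1 | df$p_cve_nonfatal > 1
  if (any(over)) {
    b <- df[over, ][1L, ]
    stop(sprintf("non-fatal probability exceeds 1 at sex '%s', age %d",
                 b$sex, as.integer(b$age)), call. = FALSE)
  }
  new_event_rates(df[c("sex", "age", RATE_COLS)])
}

# per-sex matrix view used by the engine: rows = ages 25..99, cols = RATE_COLS
rates_matrix <- function(rates, sex) {
  sub <- rates[rates$sex == sex, , drop = FALSE]
  if (nrow(sub) != length(AGES) || !all(sort(sub$age) == AGES))
    stop(sprintf("event rates incomplete for sex '%s'", sex), call. = FALSE)
  sub <- sub[order(sub$age), ]
  m <- as.matrix(sub[RATE_COLS])
  rownames(m) <- AGES
  m
}

#' Apply the treatment effect to event rates
#'
#' Multiplies all four cardiovascular event probabilities by `1 - rrr`;
#' other-cause death is unchanged.
#'
#' @param rates An `event_rates` data frame.
#' @param effect A [treatment_effect()].
#' @return The treated `event_rates`.
#' @export
apply_treatment <- function(rates, effect = treatment_effect()) {
  cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
  rates[cv] <- lapply(rates[cv], function(p) p * (1 - effect$rrr))
  rates
}

#' Effective per-cycle probabilities given event history
#'
#' Modifies a single age's event probabilities for the state occupied:
#' event-free leaves them unchanged; a coronary history multiplies both
#' coronary probabilities by `c1` and zeroes the cerebrovascular ones (no
#' transitions between event families); a cerebrovascular history does the
#' mirror image with `c2`; a history of both applies both multipliers. The
#' multiplier is applied once regardless of how many events occurred.
#' Other-cause death is never modified.
#'
#' @param p Named numeric with entries `p_chd_fatal`, `p_chd_nonfatal`,
#'   `p_cve_fatal`, `p_cve_nonfatal`, `p_other_death`.
#' @param state One of `"event_free"`, `"post_chd"`, `"post_cve"`,
#'   `"post_both"`.
#' @param mult A [history_multipliers()].
#' @return The effective probability vector.
#' @export
apply_history <- function(p, state, mult = history_multipliers()) {
  state <- match.arg(state, c("event_free", "post_chd", "post_cve", "post_both"))
  p <- unlist(p)[RATE_COLS]
  switch(state,
    event_free = p,
    post_chd = {
      p[c("p_chd_fatal", "p_chd_nonfatal")] <-
        p[c("p_chd_fatal", "p_chd_nonfatal")] * mult$c1
      p[c("p_cve_fatal", "p_cve_nonfatal")] <- 0
      p
    },
    post_cve = {
      p[c("p_cve_fatal", "p_cve_nonfatal")] <-
        p[c("p_cve_fatal", "p_cve_nonfatal")] * mult$c2
      p[c("p_chd_fatal", "p_chd_nonfatal")] <- 0
      p
    },
    post_both = {
      p[c("p_chd_fatal", "p_chd_nonfatal")] <-
        p[c("p_chd_fatal", "p_chd_nonfatal")] * mult$c1
      p[c("p_cve_fatal", "p_cve_nonfatal")] <-
        p[c("p_cve_fatal", "p_cve_nonfatal")] * mult$c2
      p
    })
}

# scale the four CV probability columns of a per-sex rate matrix by k from
# a given age onward; cap = TRUE clamps probabilities into [0, 1] (used
# inside the calibration bracket where large trial k would overflow)
scale_cv_rates <- function(m, k, from_age = AGE_MIN, cap = FALSE) {
  cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
  rows <- AGES >= from_age
  m[rows, cv] <- m[rows, cv] * k
  if (cap) m[, cv] <- pmin(m[, cv], 1)
  m
}

#' Calibrate event rates to a target 10-year combined-endpoint risk
#'
#' Finds the single scalar `k` multiplying all four cardiovascular event
#' probabilities at every age at or above the start age such that an
#' untreated, event-free cohort starting at `start_age` accumulates a
#' first combined-endpoint event (any non-fatal or fatal coronary or
#' cerebrovascular event) with probability `threshold` within 10 one-year
#' cycles. The cumulative risk is strictly increasing in `k`, so bracketed
#' bisection on `[1e-6, 1e3]` converges to a unique solution; iteration
#' stops when the achieved risk is within `tol` of the target.
#'
#' @param rates An `event_rates` data frame (both sexes).
#' @param sex `"female"` or `"male"`.
#' @param start_age Treatment start age (integer in 25-99).
#' @param threshold Target 10-year combined-endpoint probability in (0, 1).
#' @param mult A [history_multipliers()] (affects cycles after a first
#'   event, not the first-event risk itself, but is carried for engine use).
#' @param horizon Risk horizon in cycles (default 10; truncated at age 99).
#' @param tol Absolute tolerance on the achieved risk (default 1e-8).
#' @param bracket Search interval for `k`.
#' @return A list with `rates` (the calibrated `event_rates`, both sexes,
#'   with only the requested sex rescaled), `k`, and `achieved` (the
#'   attained 10-year risk).
#' @export
calibrate_risk <- function(rates, sex, start_age, threshold,
                           mult = history_multipliers(), horizon = 10L,
                           tol = 1e-8, bracket = c(1e-6, 1e3)) {
  stopifnot(threshold > 0, threshold < 1)
  sex <- match.arg(sex, SEXES)
  m <- rates_matrix(rates, sex)
  risk_at <- function(k) {
    mk <- scale_cv_rates(m, k, from_age = start_age, cap = TRUE)
    first_event_risk(mk, start_age, horizon)
  }
  lo <- bracket[1]; hi <- bracket[2]
  r_lo <- risk_at(lo); r_hi <- risk_at(hi)
  if (r_lo > threshold || r_hi < threshold)
    stop(sprintf(paste0("target risk %.4g unreachable: achievable range ",
                        "[%.4g, %.4g] for k in [%g, %g]"),
                 threshold, r_lo, r_hi, lo, hi), call. = FALSE)
  k <- NA_real_
  for (i in seq_len(200L)) {
    k <- 0.5 * (lo + hi)
    r <- risk_at(k)
    if (abs(r - threshold) <= tol) break
    if (r < threshold) lo <- k else hi <- k
  }
  mk <- scale_cv_rates(m, k, from_age = start_age, cap = FALSE)
  if (any(mk > 1 + 1e-15))
    stop("calibrated probability exceeds 1; target too aggressive for these rates",
         call. = FALSE)
  out <- rates
  idx <- out$sex == sex & out$age >= start_age
  cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
  out[idx, cv] <- lapply(out[idx, cv, drop = FALSE], function(p) p * k)
  list(rates = new_event_rates(out), k = k, achieved = risk_at(k))
}

# cumulative probability of a first combined-endpoint event within `horizon`
# cycles for an event-free person at `start_age`; competing other-cause death
# removes people from the at-risk pool. Operates on a per-sex rate matrix.
first_event_risk <- function(m, start_age, horizon = 10L) {
  ages <- start_age:min(AGE_MAX, start_age + horizon - 1L)
  alive_ef <- 1  # mass still event-free and alive
  cum <- 0
  for (a in ages) {
    p <- m[as.character(a), ]
    cf <- p[["p_chd_fatal"]]; vf <- p[["p_cve_fatal"]]
    of <- p[["p_other_death"]]
    cn <- p[["p_chd_nonfatal"]]; vn <- p[["p_cve_nonfatal"]]
    surv <- max(0, 1 - cf - vf - of)
    p_first <- cf + vf + surv * (1 - (1 - cn) * (1 - vn))
    cum <- cum + alive_ef * p_first
    alive_ef <- alive_ef * surv * (1 - cn) * (1 - vn)
  }
  cum
}

#' Ratio of cardiovascular to other-cause 10-year mortality risk
#'
#' For an event-free person at a given age, the ratio of the cumulative
#' probability of dying of a coronary or cerebrovascular event within the
#' horizon to the cumulative probability of dying of any other cause. The
#' full state dynamics (history multipliers after a first non-fatal event)
#' are taken into account. This quantifies the competing-risk burden: it
#' falls steeply with age as other-cause mortality overtakes.
#'
#' @param rates An `event_rates` data frame.
#' @param sex `"female"` or `"male"`.
#' @param age Starting age.
#' @param mult A [history_multipliers()].
#' @param horizon Horizon in one-year cycles (default 10, truncated at 99).
#' @return A single non-negative number (0 when CV rates are zero;
#'   `NaN` when both cumulative risks are zero).
#' @export
competing_risk_ratio <- function(rates, sex, age, mult = history_multipliers(),
                                 horizon = 10L) {
  traj <- run_cohort(rates, sex = sex, start_age = age, mult = mult,
                     n_cycles = horizon)
  ev <- traj$events
  cv_deaths <- sum(ev[, "fatal_chd"]) + sum(ev[, "fatal_cve"])
  other_deaths <- sum(ev[, "other_death"])
  if (other_deaths == 0 && cv_deaths == 0) return(NaN)
  cv_deaths / other_deaths
}
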