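# Microsimulation bootstrap.
#
# Individual life courses are sampled from the same cycle structure as the
# deterministic engine: a categorical death draw (fatal CHD / fatal CVE /
# other) followed, among survivors, by independent Bernoulli draws for
# non-fatal coronary and cerebrovascular events. Economic outcomes are
# accrued per individual so that percentile-bootstrap confidence intervals
# for mean QALY gains and costs can be formed; utility weights may be drawn
# per iteration from their 95% CIs (normal on the weight scale, truncated to
# [0, 1], sd = CI width / 3.92) to propagate preference uncertainty.

# per-living-state multipliers for the four CV probabilities; other-cause
# death is never modified. Cross-family rates are zero after a single-family
# history (no transitions between event families).
hist_mult_vectors <- function(mult) {
  list(chd = c(1, mult$c1, 0, mult$c1),
       cve = c(1, 0, mult$c2, mult$c2))
}

draw_utility_matrix <- function(n, weights, sample_utilities) {
  w <- matrix(rep(c(weights$w_none, weights$w_chd, weights$w_cve,
                    weights$w_both), each = n), nrow = n)
  colnames(w) <- LIVING
  if (!sample_utilities) return(w)
  draw <- function(mean, ci) {
    sd <- (ci[2] - ci[1]) / 3.92
    if (sd == 0) return(rep(mean, n))
    pmin(1, pmax(0, stats::rnorm(n, mean, sd)))
  }
  w[, "post_chd"] <- draw(weights$w_chd, weights$ci_chd)
  w[, "post_cve"] <- draw(weights$w_cve, weights$ci_cve)
  w[, "post_both"] <- draw(weights$w_both, weights$ci_both)
  w
}

#' Sample individual life courses (one arm)
#'
#' Simulates `n_iterations` independent persons starting event-free at
#' `start_age` and returns per-individual discounted QALYs, life-years,
#' statin and event costs, and first combined-endpoint event times.
#' Deterministic given `config$seed`.
#'
#' @param rates An `event_rates` data frame (calibrated as desired).
#' @param sex,start_age Cohort definition as in [run_cohort()].
#' @param treated Apply `effect` and accrue statin costs.
#' @param config A [sim_config()].
#' @param weights A [utility_weights()].
#' @param costs A [cost_params()].
#' @param effect A [treatment_effect()].
#' @param mult A [history_multipliers()].
#' @param utility_matrix Optional pre-drawn `n x 4` utility matrix (columns
#'   in living-state order); overrides `config$sample_utilities`. Used to
#'   share preference draws across arms.
#' @return A list of per-individual numeric vectors: `qaly`, `life_years`,
#'   `statin_cost`, `event_cost`, `first_event_cycle` (NA if none), plus
#'   `n` and the `ages` simulated.
#' @export
run_microsim <- function(rates, sex, start_age, treated = FALSE,
                         config = sim_config(), weights = utility_weights(),
                         costs = cost_params(), effect = treatment_effect(),
                         mult = history_multipliers(),
                         utility_matrix = NULL) {
  sex <- match.arg(sex, SEXES)
  n <- config$n_iterations
  set.seed(config$seed)
  m <- rates_matrix(rates, sex)
  if (treated) {
    cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
    m[, cv] <- m[, cv] * (1 - effect$rrr)
  }
  ages <- start_age:AGE_MAX
  n_cycles <- length(ages)
  disc <- (1 + costs$discount_rate)^(-(seq_len(n_cycles) - 1L))
  hm <- hist_mult_vectors(mult)
  if (is.null(utility_matrix))
    utility_matrix <- draw_utility_matrix(n, weights, config$sample_utilities)

  state <- rep.int(1L, n)  # indices into STATES; 1..4 living
  qaly <- numeric(n); life_years <- numeric(n)
  statin <- numeric(n); event_cost <- numeric(n)
  first_ev <- rep(NA_integer_, n)

  for (t in seq_len(n_cycles)) {
    alive <- which(state <= 4L)
    if (!length(alive)) break
    p <- m[as.character(ages[t]), ]
    st <- state[alive]
    cf <- p[["p_chd_fatal"]] * hm$chd[st]
    vf <- p[["p_cve_fatal"]] * hm$cve[st]
    of <- p[["p_other_death"]]
    cn <- p[["p_chd_nonfatal"]] * hm$chd[st]
    vn <- p[["p_cve_nonfatal"]] * hm$cve[st]
    if (any(cf + vf + of > 1) || any(cn > 1) || any(vn > 1))
      stop(sprintf("rate overflow at age %d (sex %s)", ages[t], sex),
           call. = FALSE)

    u <- stats::runif(length(alive))
    die_chd <- u < cf
    die_cve <- !die_chd & u < cf + vf
    die_oth <- !die_chd & !die_cve & u < cf + vf + of
    surv <- !(die_chd | die_cve | die_oth)

    ev_chd <- surv & stats::runif(length(alive)) < cn
    ev_cve <- surv & stats::runif(length(alive)) < vn

    # costs: fatal events in the death cycle, non-fatal per occurrence
    add_cost <- numeric(length(alive))
    add_cost[die_chd] <- add_cost[die_chd] + costs$cost_chd_fatal
    add_cost[die_cve] <- add_cost[die_cve] + costs$cost_cve_fatal
    if (costs$recurrent_costs) {
      add_cost[ev_chd] <- add_cost[ev_chd] + costs$cost_chd_nonfatal
      add_cost[ev_cve] <- add_cost[ev_cve] + costs$cost_cve_nonfatal
    } else {
      add_cost[ev_chd & st == 1L] <- add_cost[ev_chd & st == 1L] +
        costs$cost_chd_nonfatal
      add_cost[ev_cve & st == 1L] <- add_cost[ev_cve & st == 1L] +
        costs$cost_cve_nonfatal
    }
    event_cost[alive] <- event_cost[alive] + disc[t] * add_cost

    # first combined-endpoint event (from the event-free state only)
    was_ef <- st == 1L
    had_first <- was_ef & (die_chd | die_cve | ev_chd | ev_cve)
    first_ev[alive[had_first]] <- t

    # state update
    new_st <- st
    new_st[die_chd] <- 5L; new_st[die_cve] <- 6L; new_st[die_oth] <- 7L
    to_both <- was_ef & ev_chd & ev_cve
    to_chd <- was_ef & ev_chd & !ev_cve
    to_cve <- was_ef & ev_cve & !ev_chd
    new_st[to_chd] <- 2L; new_st[to_cve] <- 3L; new_st[to_both] <- 4L

    now_alive <- new_st <= 4L
    ai <- alive[now_alive]
    life_years[ai] <- life_years[ai] + 1
    qaly[ai] <- qaly[ai] +
      disc[t] * utility_matrix[cbind(ai, new_st[now_alive])]
    if (treated)
      statin[ai] <- statin[ai] + disc[t] * costs$statin_annual

    state[alive] <- new_st
  }

  list(n = n, ages = ages, qaly = qaly, life_years = life_years,
       statin_cost = statin, event_cost = event_cost,
       first_event_cycle = first_ev)
}

# percentile bootstrap CI of the mean of x
boot_ci_mean <- function(x, n_boot = 1000L, conf = 0.95) {
  n <- length(x)
  means <- vapply(seq_len(n_boot), function(i)
    mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
  a <- (1 - conf) / 2
  stats::quantile(means, c(a, 1 - a), names = FALSE)
}

#' Microsimulation outcome distribution for a treated vs untreated pair
#'
#' Runs paired treated and untreated microsimulations (sharing per-iteration
#' utility-weight draws, with independent event randomness) and summarises
#' mean outcomes with percentile-bootstrap 95% confidence intervals of the
#' mean.
#'
#' @inheritParams run_microsim
#' @param rates_untreated,rates_treated Calibrated `event_rates` for each
#'   arm (usually identical; the treatment effect is applied internally to
#'   the treated arm).
#' @return A list with per-outcome summaries (`qaly_gain`, `le_gain`,
#'   `statin_cost`, `avoided_event_cost`, each with `mean`, `ci`), the
#'   10-cycle cumulative first-event probabilities per arm, and the raw
#'   per-iteration vectors.
#' @export
microsim_outcomes <- function(rates_untreated, rates_treated = rates_untreated,
                              sex, start_age, config = sim_config(),
                              weights = utility_weights(),
                              costs = cost_params(),
                              effect = treatment_effect(),
                              mult = history_multipliers()) {
  if (config$n_iterations < 2L)
    stop("confidence intervals require `n_iterations` >= 2", call. = FALSE)
  set.seed(config$seed)
  w <- draw_utility_matrix(config$n_iterations, weights, config$sample_utilities)
  seeds <- sample.int(.Machine$integer.max, 3L)
  cfg_u <- config; cfg_u$seed <- seeds[1]
  cfg_t <- config; cfg_t$seed <- seeds[2]
  untx <- run_microsim(rates_untreated, sex, start_age, treated = FALSE,
                       config = cfg_u, weights = weights, costs = costs,
                       effect = effect, mult = mult, utility_matrix = w)
  tx <- run_microsim(rates_treated, sex, start_age, treated = TRUE,
                     config = cfg_t, weights = weights, costs = costs,
                     effect = effect, mult = mult, utility_matrix = w)
  set.seed(seeds[3])
  dq <- tx$qaly - untx$qaly
  dl <- tx$life_years - untx$life_years
  dc <- untx$event_cost - tx$event_cost
  cum10 <- function(sim) {
    h <- min(10L, length(sim$ages))
    mean(!is.na(sim$first_event_cycle) & sim$first_event_cycle <= h)
  }
  list(
    qaly_gain = list(mean = mean(dq), ci = boot_ci_mean(dq)),
    le_gain = list(mean = mean(dl), ci = boot_ci_mean(dl)),
    statin_cost = list(mean = mean(tx$statin_cost),
                       ci = boot_ci_mean(tx$statin_cost)),
    avoided_event_cost = list(mean = mean(dc), ci = boot_ci_mean(dc)),
    cum10_untreated = cum10(untx), cum10_treated = cum10(tx),
    untreated = untx, treated = tx
  )
}
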