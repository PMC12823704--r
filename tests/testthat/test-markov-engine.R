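test_that("cycle transitions compose deaths and independent non-fatal events", {
  p0 <- c(p_chd_fatal = 0, p_chd_nonfatal = 0, p_cve_fatal = 0,
          p_cve_nonfatal = 0, p_other_death = 0)
  tr <- cycle_transitions(p0, "event_free")
  expect_equal(tr[["event_free"]], 1)
  expect_equal(sum(tr), 1)

  p <- c(p_chd_fatal = 0, p_chd_nonfatal = 0.1, p_cve_fatal = 0,
         p_cve_nonfatal = 0.1, p_other_death = 0)
  tr <- cycle_transitions(p, "event_free", history_multipliers(1, 1))
  expect_equal(tr[["post_both"]], 0.01)
  expect_equal(tr[["post_chd"]], 0.09)
  expect_equal(tr[["post_cve"]], 0.09)
  expect_equal(tr[["event_free"]], 0.81)

  # conservation across random rate draws and all living states
  set.seed(42)
  for (i in 1:25) {
    p <- c(p_chd_fatal = runif(1, 0, 0.1), p_chd_nonfatal = runif(1, 0, 0.3),
           p_cve_fatal = runif(1, 0, 0.1), p_cve_nonfatal = runif(1, 0, 0.2),
           p_other_death = runif(1, 0, 0.3))
    for (st in c("event_free", "post_chd", "post_cve", "post_both"))
      expect_equal(sum(cycle_transitions(p, st)), 1, tolerance = 1e-14)
  }

  expect_error(cycle_transitions(c(p_chd_fatal = 0.5, p_chd_nonfatal = 0,
                                   p_cve_fatal = 0.4, p_cve_nonfatal = 0,
                                   p_other_death = 0.2), "event_free"),
               "overflow")
})

test_that("cohort expectation matches exhaustive path enumeration", {
  r <- const_rates(cf = 0.01, cn = 0.05, vf = 0.02, vn = 0.04, of = 0.03)
  # age-varying rates so each cycle is genuinely different
  r$p_chd_nonfatal <- r$p_chd_nonfatal + 0.001 * (r$age - 25)
  r$p_other_death <- r$p_other_death + 0.0005 * (r$age - 25)
  oracle <- enumerate_paths(r, "male", 40, 3)
  traj <- run_cohort(r, "male", 40, n_cycles = 3)
  expect_equal(unname(traj$dist), unname(oracle$dist), tolerance = 1e-12)
  expect_equal(traj$cum_first_event, oracle$cum_first_event, tolerance = 1e-12)
})

test_that("cohort trajectories conserve mass and death is absorbing", {
  r <- derive_event_rates(synthetic_life_table())
  cal <- calibrate_risk(r, "female", 40, 0.10)
  traj <- run_cohort(cal$rates, "female", 40)
  expect_true(all(abs(rowSums(traj$dist) - 1) <= 1e-12))
  dead <- rowSums(traj$dist[, c("dead_chd", "dead_cve", "dead_other")])
  expect_true(all(diff(dead) >= -1e-15))
  expect_true(all(diff(traj$cum_first_event) >= 0))
  # total deaths plus survivors at 99 account for everyone
  last <- traj$dist[nrow(traj$dist), ]
  expect_equal(sum(last), 1, tolerance = 1e-12)
})

test_that("zero hazards leave the cohort event-free and constant risk matches the closed form", {
  r0 <- const_rates()
  traj <- run_cohort(r0, "female", 25)
  expect_equal(traj$dist[nrow(traj$dist), "event_free"], c(event_free = 1))
  expect_equal(prevalence_among_living(traj),
               setNames(rep(0, 75), 25:99), tolerance = 0)

  p <- 1 - 0.925^(1 / 10)
  traj <- run_cohort(const_rates(cn = p), "male", 50, n_cycles = 10)
  expect_equal(traj$cum_first_event[10], 0.075, tolerance = 1e-12)
})

test_that("treatment lowers the cumulative first-event risk at every cycle", {
  r <- derive_event_rates(synthetic_life_table())
  cal <- calibrate_risk(r, "male", 50, 0.15)
  untx <- run_cohort(cal$rates, "male", 50)
  tx <- run_cohort(cal$rates, "male", 50, treated = TRUE)
  expect_true(all(tx$cum_first_event < untx$cum_first_event))
  prev_u <- prevalence_among_living(untx)
  prev_t <- prevalence_among_living(tx)
  expect_true(all(prev_u >= prev_t))
  expect_equal(prevalence_among_living(untx, 50),
               sum(untx$dist[2, c("post_chd", "post_cve", "post_both")]) /
                 sum(untx$dist[2, c("event_free", "post_chd", "post_cve",
                                    "post_both")]))
})

test_that("the chain is memoryless: restarting from an intermediate distribution agrees", {
  r <- derive_event_rates(synthetic_life_table())
  cal <- calibrate_risk(r, "female", 40, 0.10)
  full <- run_cohort(cal$rates, "female", 40)
  mid <- full$dist[11, ]  # after 10 cycles, about to begin age 50
  part <- run_cohort(cal$rates, "female", 50, init = mid)
  expect_equal(part$dist[-1, ], full$dist[-(1:11), ], tolerance = 1e-12)
})

test_that("post-both is unreachable when simultaneous events are impossible", {
  r <- const_rates(cf = 0.01, cn = 0.05, vf = 0.01, vn = 0, of = 0.02)
  traj <- run_cohort(r, "male", 40)
  expect_true(all(traj$dist[, "post_both"] == 0))
  expect_true(any(traj$dist[, "post_chd"] > 0))
})

test_that("microsimulation agrees with the expectation and is reproducible", {
  r <- derive_event_rates(synthetic_life_table())
  cal <- calibrate_risk(r, "male", 60, 0.15)
  det <- run_cohort(cal$rates, "male", 60)
  cfg <- sim_config(n_iterations = 20000, seed = 11, sample_utilities = FALSE)
  sim <- run_microsim(cal$rates, "male", 60, config = cfg)
  cum10 <- mean(!is.na(sim$first_event_cycle) & sim$first_event_cycle <= 10)
  se <- sqrt(0.15 * 0.85 / cfg$n_iterations)
  expect_lt(abs(cum10 - det$cum_first_event[10]), 3 * se)

  le_se <- sd(sim$life_years) / sqrt(cfg$n_iterations)
  expect_lt(abs(mean(sim$life_years) - life_expectancy(det)), 3 * le_se)

  sim2 <- run_microsim(cal$rates, "male", 60, config = cfg)
  expect_identical(sim, sim2)
})

test_that("paired microsimulation summarises gains with bootstrap intervals", {
  r <- derive_event_rates(synthetic_life_table())
  cal <- calibrate_risk(r, "female", 70, 0.15)
  out <- microsim_outcomes(cal$rates, sex = "female", start_age = 70,
                           config = sim_config(n_iterations = 4000, seed = 3))
  expect_true(out$qaly_gain$ci[1] < out$qaly_gain$mean &
                out$qaly_gain$mean < out$qaly_gain$ci[2])
  expect_gt(out$cum10_untreated, out$cum10_treated)
  expect_error(
    microsim_outcomes(cal$rates, sex = "female", start_age = 70,
                      config = sim_config(n_iterations = 1)),
    "n_iterations")

  # with fixed utilities the interval reflects event sampling only
  out0 <- microsim_outcomes(cal$rates, sex = "female", start_age = 70,
                            config = sim_config(n_iterations = 4000, seed = 3,
                                                sample_utilities = FALSE))
  expect_true(diff(out0$qaly_gain$ci) > 0)
})
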