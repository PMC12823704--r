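test_that("event rates follow the cause-split and non-fatal ratios", {
  lt <- flat_life_table(q = 0.01, f_chd = 0.2, f_cve = 0.1)
  r <- derive_event_rates(lt)
  row <- r[r$sex == "male" & r$age == 50, ]
  expect_equal(row$p_chd_fatal, 0.002)
  expect_equal(row$p_chd_nonfatal, 0.00578)
  expect_equal(row$p_cve_fatal, 0.001)
  expect_equal(row$p_cve_nonfatal, 0.00331)
  expect_equal(row$p_other_death, 0.007)

  # zero cause fractions: everything is other-cause death
  r0 <- derive_event_rates(flat_life_table(q = 0.02, f_chd = 0, f_cve = 0))
  expect_true(all(r0$p_chd_fatal == 0 & r0$p_cve_nonfatal == 0))
  expect_true(all(r0$p_other_death == 0.02))
})

test_that("fatal probabilities conserve all-cause mortality exactly", {
  lt <- synthetic_life_table()
  r <- derive_event_rates(lt)
  expect_equal(r$p_chd_fatal + r$p_cve_fatal + r$p_other_death, lt$q_all,
               tolerance = 1e-15)
})

test_that("rate overflow in derivation is reported with its location", {
  lt <- flat_life_table(q = 0.9, f_chd = 0.5, f_cve = 0.1)
  expect_error(derive_event_rates(lt), "exceeds 1.*age 25")
})

test_that("history multipliers act once, within family, on living states only", {
  p <- c(p_chd_fatal = 0.002, p_chd_nonfatal = 0.00578,
         p_cve_fatal = 0.001, p_cve_nonfatal = 0.00331,
         p_other_death = 0.007)
  expect_identical(apply_history(p, "event_free"), p)

  chd <- apply_history(p, "post_chd")
  expect_equal(chd[["p_chd_fatal"]], 0.002888)
  expect_equal(chd[["p_cve_fatal"]], 0)
  expect_equal(chd[["p_cve_nonfatal"]], 0)
  expect_equal(chd[["p_other_death"]], 0.007)

  cve <- apply_history(p, "post_cve")
  expect_equal(cve[["p_cve_nonfatal"]], 0.00331 * 2.666)
  expect_equal(cve[["p_chd_fatal"]], 0)

  both <- apply_history(p, "post_both")
  expect_equal(both[["p_chd_nonfatal"]], 0.00578 * 1.444)
  expect_equal(both[["p_cve_fatal"]], 0.001 * 2.666)

  expect_error(cycle_transitions(p, "dead_chd"), "living")
})

test_that("treatment scales the four cardiovascular probabilities only", {
  r <- const_rates(cf = 0.01, cn = 0.02, vf = 0.005, vn = 0.01, of = 0.03)
  tr <- apply_treatment(r, treatment_effect(0.30))
  expect_equal(tr$p_chd_fatal, r$p_chd_fatal * 0.7)
  expect_equal(tr$p_chd_nonfatal[1], 0.014)
  expect_equal(tr$p_other_death, r$p_other_death)
  expect_identical(apply_treatment(r, treatment_effect(0)), r)
})

test_that("treatment commutes with history application", {
  p <- c(p_chd_fatal = 0.004, p_chd_nonfatal = 0.0116,
         p_cve_fatal = 0.002, p_cve_nonfatal = 0.0066,
         p_other_death = 0.01)
  scale_tx <- function(x) {
    cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
    x[cv] <- x[cv] * 0.7
    x
  }
  for (st in c("event_free", "post_chd", "post_cve", "post_both"))
    expect_equal(apply_history(scale_tx(p), st), scale_tx(apply_history(p, st)))
})

test_that("calibration recovers the closed-form constant-hazard solution", {
  # only non-fatal coronary events, constant over age, no competing death:
  # 10-year risk 1 - (1 - p)^10 = 0.075 has solution p = 1 - 0.925^(1/10)
  r <- const_rates(cn = 0.02)
  cal <- calibrate_risk(r, "male", 40, 0.075)
  p_exact <- 1 - 0.925^(1 / 10)
  p_cal <- cal$rates$p_chd_nonfatal[cal$rates$sex == "male" &
                                      cal$rates$age == 40]
  expect_lt(abs(p_cal - p_exact), 5e-9)
  expect_lt(abs(cal$achieved - 0.075), 1e-8)
  # ages below the start age keep their original rates
  expect_equal(cal$rates$p_chd_nonfatal[cal$rates$sex == "male" &
                                          cal$rates$age == 30], 0.02)
})

test_that("calibration is a fixed point at the achieved risk and monotone in the target", {
  r <- derive_event_rates(synthetic_life_table())
  base <- statinCEA:::first_event_risk(statinCEA:::rates_matrix(r, "male"), 50)
  cal1 <- calibrate_risk(r, "male", 50, base)
  expect_equal(cal1$k, 1, tolerance = 1e-6)

  k_lo <- calibrate_risk(r, "male", 50, 0.075)$k
  k_hi <- calibrate_risk(r, "male", 50, 0.15)$k
  expect_gt(k_hi, k_lo)

  expect_error(calibrate_risk(r, "male", 50, 0.9999),
               "unreachable|exceeds 1")
})

test_that("calibration scaling equivalence matches a brute-force grid search", {
  r <- derive_event_rates(synthetic_life_table())
  cv <- c("p_chd_fatal", "p_chd_nonfatal", "p_cve_fatal", "p_cve_nonfatal")
  k0 <- 1.7
  r2 <- r
  r2[cv] <- lapply(r2[cv], function(p) p * k0)
  k <- calibrate_risk(r, "female", 60, 0.10)$k
  k2 <- calibrate_risk(r2, "female", 60, 0.10)$k
  expect_equal(k2, k / k0, tolerance = 1e-6)

  # independent oracle: dense grid search over k
  grid <- seq(0.9 * k, 1.1 * k, length.out = 4001)
  m <- statinCEA:::rates_matrix(r, "female")
  risks <- vapply(grid, function(kk)
    statinCEA:::first_event_risk(
      statinCEA:::scale_cv_rates(m, kk, from_age = 60), 60), numeric(1))
  expect_equal(k, grid[which.min(abs(risks - 0.10))],
               tolerance = diff(grid[1:2]) * 2 / k)
})

test_that("competing-risk ratio behaves at its limits and falls with age", {
  # symmetric constant hazards: fatal CV risk equals other-cause risk
  r <- const_rates(cf = 0.01, of = 0.01)
  expect_equal(competing_risk_ratio(r, "male", 50), 1, tolerance = 1e-12)

  r0 <- const_rates(of = 0.02)
  expect_equal(competing_risk_ratio(r0, "male", 50), 0)

  # in a fixed risk stratum (each age calibrated to the same 10-year risk)
  # rising other-cause mortality drives the ratio down with age
  rs <- derive_event_rates(synthetic_life_table())
  ratios <- vapply(c(40, 60, 80), function(a) {
    cal <- calibrate_risk(rs, "female", a, 0.075)
    competing_risk_ratio(cal$rates, "female", a)
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})
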