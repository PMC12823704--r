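test_that("lognormal tail share and conditional mean match numeric integration", {
  d <- risk_distribution(median_ref = c(female = 0.05, male = 0.05),
                         log_slope = 0, sdlog = 0.5)
  tl <- risk_tail(d, "male", 40, 0.075)
  expect_equal(tl$p_above, 1 - pnorm(log(0.075 / 0.05) / 0.5),
               tolerance = 1e-12)
  expect_equal(tl$p_above, 0.209, tolerance = 2e-3)

  # independent oracle: numeric integration of the truncated density
  mu <- log(0.05); s <- 0.5
  num <- integrate(function(x) x * dlnorm(x, mu, s), 0.075, 1)$value +
    1 * plnorm(1, mu, s, lower.tail = FALSE)
  expect_equal(tl$mean_above, num / tl$p_above, tolerance = 1e-6)
})

test_that("degenerate and unreachable thresholds give the contracted signals", {
  d <- risk_distribution(median_ref = c(female = 0.2, male = 0.2),
                         log_slope = 0, sdlog = 0)
  pop <- validate_population(do.call(rbind, lapply(c("female", "male"),
    function(sx) data.frame(sex = sx, age = 25:99, persons = 100))))
  sm <- treated_share_and_mean(d, 0.075, 25, pop)
  expect_equal(sm$share, 1)
  expect_equal(sm$mean_risk, 0.2)

  sm0 <- treated_share_and_mean(d, 0.5, 25, pop)
  expect_equal(sm0$share, 0)
  expect_true(is.na(sm0$mean_risk))
})

test_that("treated share and mean agree with a Monte Carlo oracle", {
  d <- risk_distribution()
  pop <- synthetic_population()
  sm <- treated_share_and_mean(d, 0.10, 50, pop)

  set.seed(99)
  n <- 4000
  num <- 0; den <- 0; tot <- 0
  for (sx in c("female", "male")) for (a in 25:99) {
    w <- pop$persons[pop$sex == sx & pop$age == a]
    tot <- tot + w
    if (a < 50) next
    mu <- log(d$median_ref[[sx]]) + d$log_slope * (min(a, d$sat_age) - 40)
    x <- pmin(rlnorm(n, mu, d$sdlog), 1)
    sel <- x > 0.10
    den <- den + w * mean(sel)
    num <- num + w * mean(x[sel]) * mean(sel)
  }
  expect_equal(sm$share, den / tot, tolerance = 0.02)
  expect_equal(sm$mean_risk, num / den, tolerance = 0.02)
})

test_that("share and mean treated risk order correctly in threshold and age", {
  d <- risk_distribution()
  pop <- synthetic_population()
  ths <- c(0.075, 0.10, 0.15)
  ages <- c(25, 40, 50, 60, 70)
  share <- outer(ths, ages, Vectorize(function(th, a)
    treated_share_and_mean(d, th, a, pop)$share))
  mean_risk <- outer(ths, ages, Vectorize(function(th, a)
    treated_share_and_mean(d, th, a, pop)$mean_risk))
  expect_true(all(apply(share, 2, diff) <= 0))       # threshold direction
  expect_true(all(apply(share, 1, diff) <= 0))       # min-age direction
  expect_true(all(mean_risk >= matrix(ths, 3, 5)))
  expect_true(all(apply(mean_risk, 1, diff) >= 0))   # rises with min age
})

test_that("budget impact is linear in share, population and price", {
  expect_equal(budget_impact(0.10, 80e6, 100), 0.8e9)
  expect_equal(budget_impact(0, 80e6, 100), 0)
  expect_equal(budget_impact(0.232, 83.2e6, 100) / 1e9, 1.93, tolerance = 5e-3)
})

test_that("cross-sex averaging weights by population sex proportions", {
  pop <- validate_population(do.call(rbind, lapply(c("female", "male"),
    function(sx) data.frame(sex = sx, age = 25:99, persons = 500))))
  expect_equal(sex_average(c(female = 2, male = 4), pop, 40), 3)

  pop1 <- pop
  pop1$persons[pop1$sex == "male" & pop1$age == 40] <- 0
  expect_equal(sex_average(c(female = 2, male = 4), pop1, 40), 2)

  # renormalisation over an age range equals a direct weighted sum
  pop2 <- synthetic_population()
  ages <- 60:80
  vals <- c(female = 1.3, male = 0.7)
  direct <- sum(vapply(c("female", "male"), function(sx)
    vals[[sx]] * sum(pop2$persons[pop2$sex == sx & pop2$age %in% ages]),
    numeric(1))) / sum(pop2$persons[pop2$age %in% ages])
  expect_equal(sex_average(vals, pop2, ages), direct, tolerance = 1e-12)
})

test_that("population life-expectancy gains aggregate per the definition", {
  # two occupied ages, 50% above threshold everywhere, gains 1.0 and 0.5
  d <- risk_distribution(median_ref = c(female = 0.075, male = 0.075),
                         log_slope = 0, sdlog = 0.4)
  pop <- do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = 25:99, persons = ifelse(25:99 %in% c(60, 70),
                                                       1000, 0))))
  gains <- do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = 25:99,
               gain = ifelse(25:99 == 60, 1.0, 0.5))))
  lp <- population_le_gain(gains, d, 0.075, pop, 25)
  expect_equal(lp$treated, 0.75)
  expect_equal(lp$total, 0.375)

  # uniform gain with everyone qualifying reproduces the gain itself
  d1 <- risk_distribution(median_ref = c(female = 0.3, male = 0.3),
                          log_slope = 0, sdlog = 0)
  gains1 <- transform(gains, gain = 0.8)
  lp1 <- population_le_gain(gains1, d1, 0.075, pop, 25)
  expect_equal(lp1$treated, 0.8)
  expect_equal(lp1$total, 0.8)

  # nobody above threshold: treated gain undefined, total zero
  d0 <- risk_distribution(median_ref = c(female = 0.001, male = 0.001),
                          log_slope = 0, sdlog = 0)
  lp0 <- population_le_gain(gains, d0, 0.5, pop, 25)
  expect_true(is.na(lp0$treated))
  expect_equal(lp0$total, 0)
})
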