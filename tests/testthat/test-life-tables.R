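test_that("synthetic mortality follows the Gompertz-Makeham closed form", {
  p <- synthetic_mortality_params(makeham_a = 0.001, gompertz_b = 2e-5,
                                  gompertz_c = 0.095,
                                  sex_scale = c(female = 1, male = 1))
  lt <- synthetic_life_table(p)
  q80 <- lt$q_all[lt$sex == "male" & lt$age == 80]
  expect_equal(q80, 0.001 + 2e-5 * exp(0.095 * 80), tolerance = 1e-12)
  expect_equal(q80, 0.0410, tolerance = 1e-3)

  # near-zero hazard limit: an all-survivor table
  p0 <- synthetic_mortality_params(makeham_a = 0, gompertz_b = 1e-300,
                                   gompertz_c = 0.095)
  lt0 <- synthetic_life_table(p0)
  expect_true(all(lt0$q_all < 1e-250))
})

test_that("synthetic q_all is strictly increasing and cause fractions rise with age", {
  for (b in c(1e-5, 3e-5)) for (c in c(0.05, 0.095)) {
    lt <- synthetic_life_table(synthetic_mortality_params(
      makeham_a = 5e-4, gompertz_b = b, gompertz_c = c))
    for (sx in c("female", "male")) {
      q <- lt$q_all[lt$sex == sx]
      expect_true(all(diff(q) > 0))
    }
  }
  lt <- synthetic_life_table()
  for (sx in c("female", "male")) {
    f30 <- lt$f_chd[lt$sex == sx & lt$age == 30]
    f80 <- lt$f_chd[lt$sex == sx & lt$age == 80]
    expect_lt(f30, f80)
    expect_true(all(lt$f_chd[lt$sex == sx] + lt$f_cve[lt$sex == sx] <= 1))
  }
})

test_that("invalid generator parameters name the offending field", {
  expect_error(synthetic_mortality_params(gompertz_b = -1), "gompertz_b")
  expect_error(synthetic_mortality_params(sex_scale = c(female = -1, male = 1)),
               "sex_scale")
  expect_error(synthetic_mortality_params(chd_asym = 0.8, cve_asym = 0.5),
               "asym")
})

test_that("life table round-trips through CSV bit-exactly", {
  lt <- synthetic_life_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_life_table(lt, path)
  lt2 <- read_life_table(path)
  expect_identical(lt2$q_all, lt$q_all)
  expect_identical(lt2$f_chd, lt$f_chd)
  expect_identical(lt2$f_cve, lt$f_cve)
  expect_equal(nrow(lt2), 150L)
})

test_that("reader validates completeness and cause-fraction consistency", {
  lt <- as.data.frame(synthetic_life_table())
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(lt[!(lt$sex == "male" & lt$age == 40), ], path, row.names = FALSE)
  expect_error(read_life_table(path), "40")

  bad <- lt
  bad$f_chd[1] <- 0.7; bad$f_cve[1] <- 0.4
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_life_table(path), "f_chd \\+ f_cve > 1")

  # ages outside 25-99 are dropped, not an error
  ext <- rbind(lt, data.frame(sex = "male", age = c(12, 104), q_all = 0.5,
                              f_chd = 0.1, f_cve = 0.1))
  write.csv(ext, path, row.names = FALSE)
  expect_equal(nrow(read_life_table(path)), 150L)
})

test_that("central mortality rates and death counts convert to probabilities", {
  lt <- as.data.frame(synthetic_life_table())
  path <- withr::local_tempfile(fileext = ".csv")

  m <- lt; m$m_all <- -log(1 - m$q_all); m$q_all <- NULL
  write.csv(m, path, row.names = FALSE)
  expect_equal(read_life_table(path)$q_all, lt$q_all, tolerance = 1e-12)

  counts <- data.frame(sex = lt$sex, age = lt$age, population = 1e5,
                       deaths_total = 1e5 * lt$q_all,
                       deaths_chd = 1e5 * lt$q_all * lt$f_chd,
                       deaths_cve = 1e5 * lt$q_all * lt$f_cve)
  write.csv(counts, path, row.names = FALSE)
  got <- read_life_table(path)
  expect_equal(got$q_all, lt$q_all, tolerance = 1e-12)
  expect_equal(got$f_chd, lt$f_chd, tolerance = 1e-12)

  # dialect remaps foreign column names
  names(counts) <- c("Geschlecht", "Alter", "population", "deaths_total",
                     "deaths_chd", "deaths_cve")
  write.csv(counts, path, row.names = FALSE)
  got <- read_life_table(path, dialect = c(sex = "Geschlecht", age = "Alter"))
  expect_equal(got$q_all, lt$q_all, tolerance = 1e-12)
})

test_that("population structure validates and reads", {
  pop <- do.call(rbind, lapply(c("female", "male"), function(sx)
    data.frame(sex = sx, age = 25:99, persons = 1000)))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(pop, path, row.names = FALSE)
  expect_equal(sum(read_population(path)$persons), 150000)

  pop$persons[3] <- -5
  write.csv(pop, path, row.names = FALSE)
  expect_error(read_population(path), ">= 0")
})

test_that("synthetic population has even sexes at 25 and a female excess in old age", {
  pop <- synthetic_population()
  pr <- sex_proportions(pop, c(25, 95))
  expect_equal(pr["male", "25"], 0.505, tolerance = 1e-9)
  expect_gt(pr["female", "95"], pr["male", "95"])
  expect_gt(pr["female", "95"], pr["female", "25"])
})
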