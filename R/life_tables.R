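#' Parameters of the synthetic mortality generator
#'
#' The generator emulates a national cause-of-death life table with a
#' Gompertz-Makeham all-cause hazard, q(age) = min(1, a + s_sex * b *
#' exp(c * age)), and logistic age curves for the fractions of deaths due to
#' coronary heart disease (CHD) and cerebrovascular disease (CVE):
#' f(age) = asymptote / (1 + exp(-slope * (age - midpoint))). Defaults are
#' calibrated to resemble recent German mortality, so that a 40-year-old's
#' combined 10-year cardiovascular risk in the 5-10% range is attainable.
#'
#' @param makeham_a Background (age-independent) annual hazard component.
#' @param gompertz_b Baseline of the exponential senescent component.
#' @param gompertz_c Log-slope of mortality per year of age.
#' @param sex_scale Named numeric, multiplicative scale on `gompertz_b` per
#'   sex; females typically below 1.
#' @param chd_asym,chd_mid,chd_slope Logistic parameters of the CHD
#'   cause-of-death fraction (per sex where named vectors are given).
#' @param cve_asym,cve_mid,cve_slope Same for the cerebrovascular fraction.
#' @return An object of class `synthetic_mortality_params`.
#' @export
synthetic_mortality_params <- function(makeham_a = 2.2e-3,
                                       gompertz_b = 3e-5,
                                       gompertz_c = 0.082,
                                       sex_scale = c(female = 0.6, male = 1.0),
                                       chd_asym = c(female = 0.19, male = 0.21),
                                       chd_mid = 10, chd_slope = 0.06,
                                       cve_asym = c(female = 0.105, male = 0.10),
                                       cve_mid = 10, cve_slope = 0.06) {
  chk_pos <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0))
      stop(sprintf("`%s` must be finite and >= 0", nm), call. = FALSE)
    x
  }
  chk_pos(makeham_a, "makeham_a"); chk_pos(gompertz_b, "gompertz_b")
  chk_pos(gompertz_c, "gompertz_c")
  if (!all(SEXES %in% names(sex_scale)) || any(sex_scale <= 0))
    stop("`sex_scale` must be positive and named for both sexes", call. = FALSE)
  expand <- function(x, nm) {
    if (length(x) == 1L && is.null(names(x))) x <- c(female = x, male = x)
    if (!all(SEXES %in% names(x)))
      stop(sprintf("`%s` must be a scalar or named for both sexes", nm), call. = FALSE)
    x[SEXES]
  }
  chd_asym <- expand(chd_asym, "chd_asym"); cve_asym <- expand(cve_asym, "cve_asym")
  if (any(chd_asym + cve_asym > 1))
    stop("cause-fraction asymptotes must satisfy chd_asym + cve_asym <= 1", call. = FALSE)
  structure(list(makeham_a = makeham_a, gompertz_b = gompertz_b,
                 gompertz_c = gompertz_c, sex_scale = sex_scale[SEXES],
                 chd_asym = chd_asym, chd_mid = chd_mid, chd_slope = chd_slope,
                 cve_asym = cve_asym, cve_mid = cve_mid, cve_slope = cve_slope),
            class = "synthetic_mortality_params")
}

new_life_table <- function(df) {
  df <- df[order(df$sex, df$age), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("life_table", "data.frame")
  df
}

#' Generate a synthetic cause-of-death life table
#'
#' Builds a complete life table over both sexes and integer ages 25-99 from
#' Gompertz-Makeham all-cause mortality and logistic cause-of-death
#' fractions. Deterministic given the parameters.
#'
#' @param params A [synthetic_mortality_params()] object.
#' @return A `life_table`: data frame with columns `sex`, `age`, `q_all`
#'   (annual all-cause death probability), `f_chd`, `f_cve` (fractions of
#'   deaths due to coronary and cerebrovascular disease).
#' @export
synthetic_life_table <- function(params = synthetic_mortality_params()) {
  if (!inherits(params, "synthetic_mortality_params"))
    params <- do.call(synthetic_mortality_params, params)
  rows <- lapply(SEXES, function(sx) {
    q <- pmin(1, params$makeham_a +
                params$sex_scale[[sx]] * params$gompertz_b *
                exp(params$gompertz_c * AGES))
    f_chd <- params$chd_asym[[sx]] /
      (1 + exp(-params$chd_slope * (AGES - params$chd_mid)))
    f_cve <- params$cve_asym[[sx]] /
      (1 + exp(-params$cve_slope * (AGES - params$cve_mid)))
    data.frame(sex = sx, age = AGES, q_all = q, f_chd = f_chd, f_cve = f_cve)
  })
  lt <- new_life_table(do.call(rbind, rows))
  validate_life_table(lt)
}

#' Validate a life table
#'
#' Checks completeness of the (sex, age 25-99) grid, probability bounds and
#' cause-fraction consistency (`f_chd + f_cve <= 1` at every age).
#'
#' @param lt A `life_table` or compatible data frame.
#' @return The validated `life_table`, invisibly usable in pipelines.
#' @export
validate_life_table <- function(lt) {
  need <- c("sex", "age", "q_all", "f_chd", "f_cve")
  miss <- setdiff(need, names(lt))
  if (length(miss))
    stop("life table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lt$sex <- as.character(lt$sex)
  if (!all(lt$sex %in% SEXES))
    stop("`sex` must be one of: ", paste(SEXES, collapse = ", "), call. = FALSE)
  for (sx in SEXES) {
    gaps <- setdiff(AGES, lt$age[lt$sex == sx])
    if (length(gaps))
      stop(sprintf("life table incomplete for sex '%s': missing ages %s", sx,
                   paste(gaps, collapse = ", ")), call. = FALSE)
  }
  dup <- duplicated(lt[c("sex", "age")])
  if (any(dup)) stop("duplicated (sex, age) rows in life table", call. = FALSE)
  if (any(lt$q_all < 0 | lt$q_all > 1))
    stop("`q_all` must lie in [0, 1]", call. = FALSE)
  if (any(lt$f_chd < 0 | lt$f_cve < 0))
    stop("cause fractions must be >= 0", call. = FALSE)
  bad <- lt$f_chd + lt$f_cve > 1 + 1e-12
  if (any(bad)) {
    b <- lt[bad, ][1L, ]
    stop(sprintf(
      "cause fractions inconsistent (f_chd + f_cve > 1) at sex '%s', age %d",
      b$sex, as.integer(b$age)), call. = FALSE)
  }
  new_life_table(as.data.frame(lt)[c("sex", "age", "q_all", "f_chd", "f_cve")])
}

#' Read a cause-of-death life table from CSV
#'
#' Reads a delimited text file in the destatis-style layout: one row per
#' (sex, age) with either an annual death probability `q_all` directly, a
#' central mortality rate `m_all` (converted via q = 1 - exp(-m)), or death
#' counts `deaths_total` with `population`, plus cause columns given either
#' as fractions (`f_chd`, `f_cve`) or counts (`deaths_chd`, `deaths_cve`).
#' Ages outside 25-99 are dropped (above 99, mortality is truncated at the
#' final modelled cycle). Column names can be remapped with `dialect`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param dialect Optional named character vector or list mapping canonical
#'   names (e.g. `q_all`) to the file's column names, or a YAML file path
#'   with the same mapping.
#' @return A validated `life_table`.
#' @export
read_life_table <- function(path, dialect = NULL) {
  df <- apply_dialect(utils::read.csv(path, stringsAsFactors = FALSE), dialect)
  if (!all(c("sex", "age") %in% names(df)))
    stop("life table file must provide `sex` and `age` columns", call. = FALSE)
  df <- df[df$age >= AGE_MIN & df$age <= AGE_MAX, , drop = FALSE]
  if (!"q_all" %in% names(df)) {
    if ("m_all" %in% names(df)) {
      df$q_all <- 1 - exp(-df$m_all)
    } else if (all(c("deaths_total", "population") %in% names(df))) {
      df$q_all <- ifelse(df$population > 0, df$deaths_total / df$population, 0)
    } else {
      stop("need `q_all`, `m_all`, or `deaths_total` + `population`", call. = FALSE)
    }
  }
  if (!"f_chd" %in% names(df)) {
    if (all(c("deaths_chd", "deaths_total") %in% names(df))) {
      df$f_chd <- ifelse(df$deaths_total > 0, df$deaths_chd / df$deaths_total, 0)
    } else stop("need `f_chd` or `deaths_chd` + `deaths_total`", call. = FALSE)
  }
  if (!"f_cve" %in% names(df)) {
    if (all(c("deaths_cve", "deaths_total") %in% names(df))) {
      df$f_cve <- ifelse(df$deaths_total > 0, df$deaths_cve / df$deaths_total, 0)
    } else stop("need `f_cve` or `deaths_cve` + `deaths_total`", call. = FALSE)
  }
  validate_life_table(df)
}

#' Write a life table to CSV
#'
#' Full-precision round-trip companion to [read_life_table()].
#'
#' @param lt A `life_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  df <- as.data.frame(lt)
  for (cl in c("q_all", "f_chd", "f_cve"))
    df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

apply_dialect <- function(df, dialect) {
  if (is.null(dialect)) return(df)
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect))
    dialect <- yaml::read_yaml(dialect)
  dialect <- unlist(dialect)
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (!src %in% names(df))
      stop(sprintf("dialect maps `%s` to missing column `%s`", canon, src),
           call. = FALSE)
    names(df)[names(df) == src] <- canon
  }
  df
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Cause-of-death life table: %d rows (ages %d-%d, both sexes)\n",
              nrow(x), min(x$age), max(x$age)))
  for (sx in unique(x$sex)) {
    sub <- x[x$sex == sx, ]
    cat(sprintf("  %-6s q_all %.5f-%.5f; f_chd up to %.3f; f_cve up to %.3f\n",
                sx, min(sub$q_all), max(sub$q_all), max(sub$f_chd),
                max(sub$f_cve)))
  }
  invisible(x)
}
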