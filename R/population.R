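#' Generate a synthetic population age/sex structure
#'
#' Emulates a national adult population pyramid by carrying a fixed birth
#' cohort per age through sex-specific survival from a life table: counts at
#' age a are proportional to survival from age 25 to a. With the default
#' mortality parameters this gives a near-even sex split at age 25 and a
#' female excess at high ages, as in real populations.
#'
#' @param lt A `life_table` supplying the survival; defaults to
#'   [synthetic_life_table()].
#' @param base_cohort Persons entering age 25 per sex per year; the default
#'   gives a 25-99 total near 62 million, similar to Germany's adult
#'   population.
#' @param male_share_at_25 Male share of the entering cohort.
#' @return A `population_structure`: data frame with columns `sex`, `age`,
#'   `persons`.
#' @export
synthetic_population <- function(lt = synthetic_life_table(),
                                 base_cohort = 5.1e5,
                                 male_share_at_25 = 0.505) {
  lt <- validate_life_table(lt)
  rows <- lapply(SEXES, function(sx) {
    q <- lt$q_all[lt$sex == sx][order(lt$age[lt$sex == sx])]
    surv <- cumprod(c(1, 1 - q[-length(q)]))
    share <- if (sx == "male") male_share_at_25 else 1 - male_share_at_25
    data.frame(sex = sx, age = AGES, persons = 2 * base_cohort * share * surv)
  })
  validate_population(do.call(rbind, rows))
}

#' Validate a population structure
#'
#' @param pop Data frame with columns `sex`, `age`, `persons`.
#' @return A validated `population_structure`.
#' @export
validate_population <- function(pop) {
  need <- c("sex", "age", "persons")
  miss <- setdiff(need, names(pop))
  if (length(miss))
    stop("population structure missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  pop$sex <- as.character(pop$sex)
  if (!all(pop$sex %in% SEXES))
    stop("`sex` must be one of: ", paste(SEXES, collapse = ", "), call. = FALSE)
  for (sx in SEXES) {
    gaps <- setdiff(AGES, pop$age[pop$sex == sx])
    if (length(gaps))
      stop(sprintf("population incomplete for sex '%s': missing ages %s", sx,
                   paste(gaps, collapse = ", ")), call. = FALSE)
    if (!any(pop$persons[pop$sex == sx] > 0))
      stop(sprintf("sex '%s' has no positive counts", sx), call. = FALSE)
  }
  if (any(!is.finite(pop$persons)) || any(pop$persons < 0))
    stop("`persons` must be finite and >= 0", call. = FALSE)
  pop <- as.data.frame(pop)[c("sex", "age", "persons")]
  pop <- pop[order(pop$sex, pop$age), , drop = FALSE]
  rownames(pop) <- NULL
  class(pop) <- c("population_structure", "data.frame")
  pop
}

#' Read a population structure from CSV
#'
#' @param path Path to a UTF-8 CSV with columns mappable to `sex`, `age`,
#'   `persons` (or `population`).
#' @param dialect Optional column mapping as in [read_life_table()].
#' @return A validated `population_structure`.
#' @export
read_population <- function(path, dialect = NULL) {
  df <- apply_dialect(utils::read.csv(path, stringsAsFactors = FALSE), dialect)
  if (!"persons" %in% names(df) && "population" %in% names(df))
    names(df)[names(df) == "population"] <- "persons"
  df <- df[df$age >= AGE_MIN & df$age <= AGE_MAX, , drop = FALSE]
  validate_population(df)
}

# population weights helpers ------------------------------------------------

pop_lookup <- function(pop, sex, ages) {
  idx <- match(paste(sex, ages), paste(pop$sex, pop$age))
  pop$persons[idx]
}

#' Sex proportions per year of life
#'
#' @param pop A `population_structure`.
#' @param ages Integer ages of interest.
#' @return Matrix with rows `female`, `male` and one column per age, columns
#'   summing to 1.
#' @export
sex_proportions <- function(pop, ages = AGES) {
  pop <- validate_population(pop)
  m <- rbind(female = pop_lookup(pop, "female", ages),
             male = pop_lookup(pop, "male", ages))
  colnames(m) <- ages
  tot <- colSums(m)
  if (any(tot <= 0)) stop("no persons at some requested age", call. = FALSE)
  sweep(m, 2, tot, "/")
}

#' Cross-sex average of per-sex outcome values
#'
#' Weighted mean of a per-sex quantity, with weights equal to the population
#' sex proportions aggregated over the ages involved (a single treatment
#' start age for cohort outcomes, or an age range for population-level
#' quantities). Weights renormalise to 1 over the supplied ages.
#'
#' @param values Named numeric of length 2 (`female`, `male`).
#' @param pop A `population_structure`.
#' @param ages Integer ages defining the weights.
#' @return A single numeric value.
#' @export
sex_average <- function(values, pop, ages) {
  if (!all(SEXES %in% names(values)))
    stop("`values` must be named for both sexes", call. = FALSE)
  pop <- validate_population(pop)
  w <- vapply(SEXES, function(sx) sum(pop_lookup(pop, sx, ages)), numeric(1))
  if (sum(w) <= 0) stop("zero population over the requested ages", call. = FALSE)
  sum(unlist(values[SEXES]) * w) / sum(w)
}
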