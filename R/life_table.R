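#' Build a Gompertz-Makeham cohort life table
#'
#' Annual other-cause death probabilities derived from the continuous hazard
#' h(age) = a + b * exp(c * age), integrated over each year of age and
#' capped so that everyone dies by `max_age`. The defaults approximate
#' all-cause mortality of a recent US birth cohort with realistic old-age
#' acceleration; CRC mortality is simulated separately, so strictly this is
#' an all-other-cause table.
#'
#' @param makeham_a background (age-independent) hazard, per year.
#' @param gompertz_b senescent hazard scale, per year.
#' @param gompertz_c senescent hazard log-slope, per year of age.
#' @param max_age terminal age; the death probability there is 1.
#' @return a `crc_life_table`: data.frame with columns `age` (0..max_age)
#'   and `annual_death_prob`.
#' @examples
#' lt <- make_life_table()
#' lt[lt$age %in% c(50, 80), ]
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                            gompertz_c = 0.09, max_age = 100) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c >= 0, max_age > 1)
  age <- 0:max_age
  # integral of the hazard over [age, age + 1)
  cumh <- if (gompertz_c > 0) {
    makeham_a + gompertz_b / gompertz_c *
      (exp(gompertz_c * (age + 1)) - exp(gompertz_c * age))
  } else {
    makeham_a + gompertz_b
  }
  q <- pmin(1, 1 - exp(-cumh))
  q[length(q)] <- 1
  new_life_table(data.frame(age = age, annual_death_prob = q))
}

new_life_table <- function(df) {
  structure(df, class = c("crc_life_table", "data.frame"))
}

#' Read or write a life table as a two-column CSV
#'
#' @param path file path.
#' @return `read_life_table` returns a `crc_life_table`.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("age", "annual_death_prob") %in% names(df)))
  validate_life_table(new_life_table(df[, c("age", "annual_death_prob")]))
}

#' @rdname read_life_table
#' @param life_table a `crc_life_table`.
#' @export
write_life_table <- function(life_table, path) {
  utils::write.csv(as.data.frame(life_table), path, row.names = FALSE)
  invisible(path)
}

validate_life_table <- function(lt) {
  q <- lt$annual_death_prob
  if (any(q < 0 | q > 1)) stop("life table probabilities must be in [0, 1]")
  if (q[length(q)] != 1) stop("terminal age must have death probability 1")
  if (!identical(as.integer(lt$age), seq(0L, nrow(lt) - 1L)))
    stop("life table ages must be consecutive integers starting at 0")
  lt
}

# P(death age < a + 1) for a = 0..max_age; used by the sampling engine
death_cdf <- function(life_table) {
  q <- life_table$annual_death_prob
  1 - cumprod(1 - q)
}

#' Sample other-cause death ages from a life table
#'
#' Draws a discrete year of death from the life-table hazard and adds a
#' uniform within-year offset. `other_cause_death_age` draws for a single
#' person from their private substream; `sample_death_ages` draws a whole
#' population (persons 1..n) in one call.
#'
#' @param life_table a `crc_life_table`.
#' @param rng a `crc_rng` stream (see [crc_rng()]).
#' @return death age in (0, max_age].
#' @export
other_cause_death_age <- function(life_table, rng) {
  validate_life_table(life_table)
  u <- rng$unif(0, 0:1)
  cdf <- death_cdf(life_table)
  yr <- findInterval(u[1], cdf, left.open = TRUE)  # count of years with cdf < u
  min(yr + u[2], max(life_table$age))
}

#' @rdname other_cause_death_age
#' @param n number of persons.
#' @param seed root seed.
#' @export
sample_death_ages <- function(life_table, n, seed) {
  validate_life_table(life_table)
  cdf <- death_cdf(life_table)
  vapply(seq_len(n), function(i) {
    u <- rng_uniforms(seed, i, 0, 0:1)
    min(findInterval(u[1], cdf, left.open = TRUE) + u[2], max(life_table$age))
  }, numeric(1))
}

#' Expected remaining life years implied by a life table
#'
#' Closed-form expectation of the death-age sampling scheme (discrete year
#' plus uniform within-year offset), conditional on being alive at
#' `from_age`, minus `from_age`. Used as the independent oracle for
#' life-year accounting when cancer is switched off.
#'
#' @param life_table a `crc_life_table`.
#' @param from_age conditioning age (integer).
#' @return expected remaining years.
#' @export
life_table_expectation <- function(life_table, from_age = 0) {
  q <- life_table$annual_death_prob
  ages <- life_table$age
  keep <- ages >= from_age
  q <- q[keep]; ages <- ages[keep]
  surv <- cumprod(c(1, 1 - q))[seq_along(q)]  # P(alive at start of year)
  p_die <- surv * q
  p_die <- p_die / sum(p_die)
  # mid-year deaths, except in the terminal year where ages are capped
  sum(p_die * pmin(ages + 0.5, max(ages))) - from_age
}
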