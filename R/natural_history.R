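#' Generate an unscreened population of life histories
#'
#' Simulates `n` independent adenoma-carcinoma life histories under a
#' preset, with other-cause death ages drawn from the life table. Each
#' person's history is a pure function of (seed, person id), so the first
#' `k` persons of an `n`-person run equal a `k`-person run, and the same
#' person is identical in every scenario that later consumes the
#' population.
#'
#' @param preset a [crc_preset()].
#' @param life_table a [make_life_table()] table.
#' @param birth_year calendar birth year of the cohort (age is
#'   `calendar - birth_year`).
#' @param n number of persons.
#' @param seed root seed.
#' @param person_offset id offset; person ids are
#'   `person_offset + 1:n`.
#' @return object of class `crc_population`: per-person vectors
#'   (`oc_death_age`, `frailty`, `n_lesions`) and flat per-lesion vectors
#'   (`lesion_person`, `onset_age`, `t6`, `t10`, `transform_age`,
#'   `sojourn`, `clinical_age`, `surv_u`, `within_reach`), plus metadata.
#' @export
generate_population <- function(preset, life_table = make_life_table(),
                                birth_year = 1970, n, seed,
                                person_offset = 0) {
  validate_preset(preset)
  validate_life_table(life_table)
  stopifnot(n >= 1)
  pop <- cpp_generate_population(preset_engine_pars(preset),
                                 death_cdf(life_table),
                                 max(life_table$age), as.integer(n),
                                 as.double(seed), as.double(person_offset))
  pop$preset_label <- preset$label
  pop$birth_year <- birth_year
  pop$n <- as.integer(n)
  pop$seed <- seed
  pop$person_offset <- person_offset
  class(pop) <- "crc_population"
  pop
}

#' @export
print.crc_population <- function(x, ...) {
  cat("<crc_population> n =", x$n, "persons, preset", x$preset_label,
      ", seed", x$seed, "\n")
  cat("  mean lesions/person:", round(mean(x$n_lesions), 3),
      "; persons with >=1 lesion:",
      round(mean(x$n_lesions > 0), 3), "\n")
  u <- unscreened_outcomes(x)
  cat("  lifetime clinical CRC incidence (unscreened):",
      round(mean(!is.na(u$dx_age)), 4), "\n")
  invisible(x)
}

#' Flatten a population to one row per person
#'
#' Key event ages of the unscreened history, suitable for export to the
#' outcomes accounting: other-cause death age, first preclinical onset,
#' first clinical diagnosis age, CRC death age, realized death age and
#' cause, absent screening.
#'
#' @param x a `crc_population`.
#' @param ... unused.
#' @return data.frame with one row per person.
#' @export
as.data.frame.crc_population <- function(x, ...) {
  u <- unscreened_outcomes(x)
  first_event <- function(v) {
    out <- rep(NA_real_, x$n)
    ok <- is.finite(v)
    if (any(ok)) {
      sp <- tapply(v[ok], x$lesion_person[ok], min)
      out[as.integer(names(sp))] <- sp
    }
    out
  }
  data.frame(person_id = x$person_offset + seq_len(x$n),
             birth_year = x$birth_year,
             n_adenomas = x$n_lesions,
             other_cause_death_age = x$oc_death_age,
             preclinical_onset_age = first_event(x$transform_age),
             clinical_dx_age = u$dx_age,
             crc_death_age = u$crc_death_age,
             death_age = u$death_age,
             cause = ifelse(u$crc_death == 1, "CRC", "other"))
}

#' Outcomes of a population in the absence of any screening
#'
#' Replays the population against an empty exam schedule: cancers surface
#' clinically or not at all.
#'
#' @param population a `crc_population`.
#' @param preset the preset used to generate it (for survival parameters);
#'   defaults to the bundled preset with the population's label.
#' @return list of per-person vectors (`death_age`, `dx_age`,
#'   `crc_death_age`, `dx_mode`, `crc_death`).
#' @export
unscreened_outcomes <- function(population, preset = NULL) {
  if (is.null(preset)) preset <- default_presets()[[population$preset_label]]
  run_schedule(population, empty_schedule(), preset,
               sensitivity = "high")
}

#' Simulate one unscreened life history
#'
#' Single-person wrapper around the population generator, returning a
#' readable object: the person's adenomas (onset ages, growth thresholds,
#' transformation and clinical surfacing ages), death ages and cause.
#'
#' @inheritParams generate_population
#' @param person_id the person's id (their substream key).
#' @return object of class `crc_life_history`.
#' @export
simulate_life_history <- function(preset, life_table = make_life_table(),
                                  birth_year = 1970, person_id = 1,
                                  seed = 1) {
  pop <- generate_population(preset, life_table, birth_year, n = 1,
                             seed = seed, person_offset = person_id - 1)
  u <- unscreened_outcomes(pop, preset)
  adenomas <- data.frame(onset_age = pop$onset_age, t6 = pop$t6,
                         t10 = pop$t10,
                         transform_age = pop$transform_age,
                         sojourn = pop$sojourn,
                         clinical_age = pop$clinical_age,
                         surv_u = pop$surv_u,
                         within_reach = pop$within_reach == 1)
  structure(list(person_id = person_id, birth_year = birth_year,
                 preset_label = preset$label,
                 frailty = pop$frailty[1],
                 adenomas = adenomas,
                 other_cause_death_age = pop$oc_death_age[1],
                 clinical_dx_age = u$dx_age[1],
                 crc_death_age = u$crc_death_age[1],
                 death_age = u$death_age[1],
                 cause = if (u$crc_death[1] == 1) "CRC" else "other"),
            class = "crc_life_history")
}

#' @export
print.crc_life_history <- function(x, ...) {
  cat("<crc_life_history> person", x$person_id, "(", x$preset_label, ")\n")
  cat("  adenomas:", nrow(x$adenomas),
      "; other-cause death age:", round(x$other_cause_death_age, 2), "\n")
  if (!is.na(x$clinical_dx_age))
    cat("  clinical CRC diagnosis at", round(x$clinical_dx_age, 2), "\n")
  cat("  death at", round(x$death_age, 2), "cause", x$cause, "\n")
  invisible(x)
}

#' Size class of an adenoma at a given age
#'
#' Lesions start at 1 mm and grow exponentially in diameter at a per-lesion
#' rate; the class boundaries are 6 mm and 10 mm, so the class is monotone
#' non-decreasing in age for a fixed lesion.
#'
#' @param adenoma a list/row with `onset_age`, `t6`, `t10` (years from
#'   onset to the 6 mm and 10 mm thresholds).
#' @param age exam age; must be `>= onset_age`.
#' @return `"1-5mm"`, `"6-9mm"` or `">=10mm"`.
#' @export
lesion_size_class <- function(adenoma, age) {
  if (any(age < adenoma$onset_age - 1e-12))
    stop("age must not precede the lesion's onset age")
  dt <- age - adenoma$onset_age
  ifelse(dt < adenoma$t6, "1-5mm", ifelse(dt < adenoma$t10, "6-9mm", ">=10mm"))
}

#' Sample a CRC death age given a diagnosis
#'
#' Lognormal survival after diagnosis; the screen-detected parameterization
#' stochastically dominates the clinically detected one because both are
#' evaluated at the same survival quantile with a larger meanlog.
#'
#' @param preset a [crc_preset()].
#' @param clinical_dx_age age at diagnosis.
#' @param detection_mode "screen" or "clinical".
#' @param u survival quantile in (0, 1) (the lesion's `surv_u` draw).
#' @return death age (> `clinical_dx_age`).
#' @export
crc_death_age <- function(preset, clinical_dx_age,
                          detection_mode = c("clinical", "screen"), u) {
  detection_mode <- match.arg(detection_mode)
  s <- preset$crc_survival
  ml <- if (detection_mode == "screen") s$screen_meanlog else s$clin_meanlog
  clinical_dx_age + stats::qlnorm(u, ml, s$sdlog)
}

#' Digest of a population's event ages
#'
#' MD5 digest over all event ages quantized to 1e-9 years, providing a
#' platform-stable fingerprint for reproducibility tests.
#'
#' @param population a `crc_population`.
#' @return md5 hex string.
#' @export
population_digest <- function(population) {
  vals <- c(population$oc_death_age, population$onset_age,
            population$transform_age, population$clinical_age)
  vals[!is.finite(vals)] <- -1
  txt <- sprintf("%.9f", round(vals, 9))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}
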