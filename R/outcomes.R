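#' Life-years per 1000 persons
#'
#' Mean remaining life-years from the accounting anchor (the beginning of
#' 2020), truncated at zero, scaled per 1000 persons. Undiscounted.
#'
#' @param death_ages realized death ages.
#' @param anchor_age cohort age at the anchor.
#' @return life-years per 1000 persons.
#' @export
life_years <- function(death_ages, anchor_age) {
  if (length(death_ages) == 0) stop("empty population")
  1000 * mean(pmax(death_ages - anchor_age, 0))
}

#' Outcome accounting for one scenario
#'
#' `outcome_set()` builds the full outcome record from per-person
#' life-year vectors computed on the same persons under common random
#' numbers; `outcome_table()` is the scalar version used when the three
#' life-year aggregates are already known (for example from a published
#' table). The identities hold exactly by construction:
#' LYL = LYND - LY, LYG = LYND - LYNS, and %LY lost = 100 * LYL / LYG
#' whenever LYG > 0 (undefined and reported as `NA` otherwise).
#'
#' @param ly,lyns,lynd per-person remaining life-years under the disrupted
#'   scenario, no screening, and no disruption.
#' @param cases_per_1000,deaths_per_1000 lifetime CRC cases and CRC deaths
#'   per 1000 persons under the disrupted scenario.
#' @param scenario_label,preset_label,sensitivity identifiers.
#' @return object of class `crc_outcome_set` with fields `LY`, `LYNS`,
#'   `LYND`, `LYL`, `LYG_no_disruption`, `pct_LY_lost` (per 1000 persons),
#'   CRC counts, `n`, and Monte-Carlo standard errors `mc_se` (per-person
#'   jackknife form, i.e. sd/sqrt(n), with paired differences for the LYL
#'   and LYG contrasts).
#' @export
outcome_set <- function(ly, lyns, lynd, cases_per_1000, deaths_per_1000,
                        scenario_label = NA, preset_label = NA,
                        sensitivity = NA) {
  n <- length(ly)
  if (n == 0) stop("empty population")
  stopifnot(length(lyns) == n, length(lynd) == n)
  LY <- 1000 * mean(ly)
  LYNS <- 1000 * mean(lyns)
  LYND <- 1000 * mean(lynd)
  out <- outcome_table(LY, LYNS, LYND, cases_per_1000, deaths_per_1000,
                       scenario_label, preset_label, sensitivity)
  out$n <- n
  out$mc_se <- c(LY = 1000 * stats::sd(ly) / sqrt(n),
                 LYL = 1000 * stats::sd(lynd - ly) / sqrt(n),
                 LYG = 1000 * stats::sd(lynd - lyns) / sqrt(n))
  out
}

#' @rdname outcome_set
#' @param LY,LYNS,LYND life-years per 1000 persons (scenario, no
#'   screening, no disruption).
#' @export
outcome_table <- function(LY, LYNS, LYND, cases_per_1000 = NA_real_,
                          deaths_per_1000 = NA_real_,
                          scenario_label = NA, preset_label = NA,
                          sensitivity = NA) {
  LYL <- LYND - LY
  LYG <- LYND - LYNS
  pct <- if (!is.na(LYG) && LYG > 0) 100 * LYL / LYG else NA_real_
  structure(list(scenario_label = scenario_label,
                 preset_label = preset_label, sensitivity = sensitivity,
                 n = NA_integer_, LY = LY, LYNS = LYNS, LYND = LYND,
                 LYL = LYL, LYG_no_disruption = LYG, pct_LY_lost = pct,
                 crc_cases_per_1000 = cases_per_1000,
                 crc_deaths_per_1000 = deaths_per_1000,
                 mc_se = c(LY = NA_real_, LYL = NA_real_, LYG = NA_real_)),
            class = "crc_outcome_set")
}

#' @export
print.crc_outcome_set <- function(x, ...) {
  cat("<crc_outcome_set>", x$scenario_label, "/", x$preset_label, "\n")
  cat(sprintf("  LYNS %.1f  LYND %.1f  LY %.1f  (per 1000)\n",
              x$LYNS, x$LYND, x$LY))
  cat(sprintf("  LYL %.1f  LYG %.1f  %%LY lost %s\n", x$LYL,
              x$LYG_no_disruption,
              if (is.na(x$pct_LY_lost)) "NA"
              else sprintf("%.1f", x$pct_LY_lost)))
  invisible(x)
}

#' Relative risk of lifetime CRC between two scenarios
#'
#' Ratio of per-1000 lifetime CRC cases (or deaths) computed on common
#' random numbers.
#'
#' @param scenario_rate,reference_rate per-1000 counts.
#' @return the ratio; `NA` when the reference count is zero.
#' @export
relative_risk <- function(scenario_rate, reference_rate) {
  if (is.na(reference_rate) || reference_rate == 0) return(NA_real_)
  scenario_rate / reference_rate
}

#' Min-max range of outcomes across model presets
#'
#' @param outcomes list of `crc_outcome_set` objects (>= 2 presets, or one
#'   for a degenerate range).
#' @param fields outcome fields to range over.
#' @return data.frame with one row per field: `min`, `max`.
#' @export
comparative_range <- function(outcomes,
                              fields = c("LY", "LYNS", "LYND", "LYL",
                                         "LYG_no_disruption", "pct_LY_lost",
                                         "crc_cases_per_1000",
                                         "crc_deaths_per_1000")) {
  vals <- vapply(fields, function(f)
    range(vapply(outcomes, function(o) as.numeric(o[[f]]), numeric(1)),
          na.rm = FALSE),
    numeric(2))
  data.frame(outcome = fields, min = vals[1, ], max = vals[2, ],
             row.names = NULL)
}

#' Convert life-years lost per 1000 persons to life-days per person
#'
#' @param lyl_per_1000 life-years per 1000 persons.
#' @return days per person (`lyl / 1000 * 365.25`).
#' @export
life_days_per_person <- function(lyl_per_1000) {
  lyl_per_1000 / 1000 * 365.25
}
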