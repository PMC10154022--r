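#' Replay a population against an exam schedule
#'
#' Low-level bridge to the replay engine: runs every person's natural
#' history against a planned exam schedule plus the surveillance state
#' machine, and returns realized per-person outcomes. Most users want
#' [run_scenario()] or [run_experiment()] instead.
#'
#' @param population a [generate_population()] object.
#' @param schedule data.frame (`age`, `modality`) of planned routine exams,
#'   chronological; an empty schedule gives the unscreened outcomes.
#' @param preset the [crc_preset()] the population was generated from
#'   (survival parameters and FIT profile).
#' @param sensitivity colonoscopy sensitivity scenario, "high" or "low".
#' @param surveillance a [surveillance_table()].
#' @param pandemic_age cohort age at pandemic onset (delay/cutoff anchor).
#' @param delay_years length of the post-pandemic delay window; due
#'   surveillance exams inside the window are postponed to its end.
#' @param cutoff_age exams at or after this age are cancelled (used by
#'   discontinuation scenarios; surveillance included).
#' @param engine "cpp" (compiled) or "R" (reference implementation; slow,
#'   used for cross-validation).
#' @param resume_gap years until screening resumes after a normal first
#'   colonoscopy.
#' @param surveillance_stop_age see [apply_stopping_rules()].
#' @param colo_profile,fit_profile optional [test_profile()] overrides for
#'   the colonoscopy and FIT operating characteristics (defaults: the
#'   bundled profile for `sensitivity` and the preset's FIT profile).
#' @return list of per-person vectors: `death_age`, `dx_age`,
#'   `crc_death_age`, `dx_mode` (0 none / 1 screen / 2 clinical),
#'   `crc_death`, `n_colonoscopies`, `n_fits`.
#' @export
run_schedule <- function(population, schedule, preset,
                         sensitivity = c("high", "low"),
                         surveillance = surveillance_table(),
                         pandemic_age = Inf, delay_years = 0,
                         cutoff_age = Inf, engine = c("cpp", "R"),
                         resume_gap = 10, surveillance_stop_age = 85,
                         colo_profile = NULL, fit_profile = NULL) {
  sensitivity <- match.arg(sensitivity)
  engine <- match.arg(engine)
  colo <- colo_profile %||% colonoscopy_profile(sensitivity)
  fitp <- fit_profile %||% fit_profile_for(preset)
  sched <- schedule[order(schedule$age), , drop = FALSE]
  mod <- ifelse(sched$modality == "fit", 1L, 0L)

  ivm <- matrix(1000L, 6, 6)
  tb <- unclass(surveillance)
  tb[is.na(tb)] <- 1000L
  ivm[, 2:6] <- tb
  surv_pars <- list(clin_meanlog = preset$crc_survival$clin_meanlog,
                    screen_meanlog = preset$crc_survival$screen_meanlog,
                    sdlog = preset$crc_survival$sdlog)
  args <- list(population, as.double(sched$age), mod,
               c(colo$sens_small, colo$sens_medium, colo$sens_large,
                 colo$sens_preclinical[1]),
               c(fitp$sens_small, fitp$sens_medium, fitp$sens_large,
                 fitp$sens_preclinical[1], fitp$sens_preclinical[2]),
               fitp$specificity,
               as.integer(fitp$positivity_mode == "per_lesion"),
               ivm, resume_gap, surveillance_stop_age,
               pandemic_age, delay_years, cutoff_age, surv_pars,
               as.double(population$seed))
  if (engine == "cpp") do.call(cpp_run_scenario, args)
  else do.call(run_scenario_r_engine, args)
}

#' Run a disruption scenario with its counterfactuals
#'
#' Simulates the scenario's cohort under three arms sharing each person's
#' natural history (common random numbers): no screening (LYNS), the
#' no-disruption counterfactual (LYND) and the disrupted schedule (LY).
#' Cohort membership is conditioned on being alive and CRC-free at
#' pandemic onset under the no-disruption history (the pre-pandemic
#' segment is identical across screened arms, so inclusion is
#' arm-invariant). Life-years are accrued from the beginning of 2020.
#'
#' @param scenario a [parse_scenario_code()] object (or label string).
#' @param preset a [crc_preset()] (or its label).
#' @param n population size simulated.
#' @param seed root seed for the population substreams.
#' @param sensitivity colonoscopy sensitivity scenario.
#' @param life_table a [make_life_table()] table.
#' @param population optionally a pre-generated `crc_population` for this
#'   preset (cohorts share populations within a preset).
#' @param engine "cpp" or "R".
#' @return object of class `crc_scenario_run`: the [outcome_set()] plus
#'   per-person arm results and the inclusion mask.
#' @examples
#' \donttest{
#' run <- run_scenario("C60 | U", preset = "preset-A", n = 2000, seed = 1)
#' print(run)
#' }
#' @export
run_scenario <- function(scenario, preset = "preset-A", n = 10000,
                         seed = 1, sensitivity = c("high", "low"),
                         life_table = make_life_table(),
                         population = NULL, engine = c("cpp", "R")) {
  if (is.character(scenario)) scenario <- parse_scenario_code(scenario)
  if (is.character(preset)) preset <- default_presets()[[preset]]
  sensitivity <- match.arg(sensitivity)
  engine <- match.arg(engine)
  cohort <- scenario$cohort
  if (is.null(population))
    population <- generate_population(preset, life_table,
                                      cohort$birth_year, n, seed)
  cf <- build_counterfactual_schedule(cohort, scenario$modality)
  dis <- apply_disruption(cf, scenario$disruption, cohort$age_2020)
  delay_years <- switch(scenario$disruption$type,
    short_delay = , switch_to_fit = scenario$disruption$delay_months / 12,
    long_delay_to_age = scenario$disruption$resume_age - cohort$age_2020,
    0)
  cutoff <- if (scenario$disruption$type == "discontinue")
    cohort$age_2020 else Inf

  arm <- function(sched, delay = 0, cut = Inf)
    run_schedule(population, sched, preset, sensitivity,
                 pandemic_age = cohort$age_2020, delay_years = delay,
                 cutoff_age = cut, engine = engine)
  ns <- arm(empty_schedule())
  nd <- arm(cf)
  dd <- if (scenario$disruption$type == "none") nd
        else arm(dis, delay = delay_years, cut = cutoff)

  included <- nd$death_age > cohort$age_2020 &
    (is.na(nd$dx_age) | nd$dx_age >= cohort$age_2020 - 1e-9)
  anchor <- cohort$age_2020 - 0.25
  ly <- function(a) pmax(a$death_age[included] - anchor, 0)
  oset <- outcome_set(ly(dd), ly(ns), ly(nd),
                      cases_per_1000 = 1000 * mean(!is.na(dd$dx_age[included])),
                      deaths_per_1000 = 1000 * mean(dd$crc_death[included] == 1),
                      scenario_label = scenario$label,
                      preset_label = preset$label,
                      sensitivity = sensitivity)
  structure(list(outcomes = oset, scenario = scenario,
                 preset_label = preset$label, sensitivity = sensitivity,
                 n_simulated = population$n, included = included,
                 arms = list(no_screening = ns, no_disruption = nd,
                             disrupted = dd),
                 schedule = dis, counterfactual_schedule = cf,
                 seed = seed),
            class = "crc_scenario_run")
}

#' @export
print.crc_scenario_run <- function(x, ...) {
  o <- x$outcomes
  cat("<crc_scenario_run>", o$scenario_label, "/", o$preset_label,
      paste0("(", x$sensitivity, " colonoscopy sensitivity)"), "\n")
  cat("  cohort n =", o$n, "included of", x$n_simulated, "simulated\n")
  cat(sprintf("  LY per 1000:    %10.1f  (no disruption %.1f, no screening %.1f)\n",
              o$LY, o$LYND, o$LYNS))
  cat(sprintf("  LYL per 1000:   %10.1f  (MC SE %.1f);  %.1f life-days/person\n",
              o$LYL, o$mc_se["LYL"], life_days_per_person(o$LYL)))
  cat(sprintf("  LYG (no disr.): %10.1f  (MC SE %.1f);  %%LY lost: %s\n",
              o$LYG_no_disruption, o$mc_se["LYG"],
              if (is.na(o$pct_LY_lost)) "undefined"
              else sprintf("%.1f%%", o$pct_LY_lost)))
  cat(sprintf("  CRC per 1000:   %10.1f cases, %.1f deaths\n",
              o$crc_cases_per_1000, o$crc_deaths_per_1000))
  invisible(x)
}
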