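#' Study cohorts
#'
#' The eight pre-pandemic cohorts, defined by age in April 2020 and
#' pre-pandemic screening: U50/U60/U70 unscreened, C60 (colonoscopy at 50),
#' C70 (colonoscopies at 50 and 60), F60 (annual FIT 50-59), f60
#' (biennial FIT at 50, 52, 54, 56), F70 (annual FIT 50-69). The package
#' anchors calendar time so that a person's age equals the cohort age
#' exactly at pandemic onset (April 2020, calendar 2020.25); life-years are
#' accrued from the beginning of 2020, i.e. from age `age_2020 - 0.25`.
#'
#' @param code one of "U50", "U60", "C60", "F60", "f60", "U70", "C70",
#'   "F70".
#' @return object of class `crc_cohort`: code, `age_2020`, `birth_year`
#'   and a data.frame of pre-pandemic exams (`age`, `modality`).
#' @export
cohort_spec <- function(code) {
  defs <- list(
    U50 = list(age = 50, pre = NULL),
    U60 = list(age = 60, pre = NULL),
    C60 = list(age = 60, pre = data.frame(age = 50, modality = "colonoscopy")),
    F60 = list(age = 60, pre = data.frame(age = 50:59, modality = "fit")),
    f60 = list(age = 60, pre = data.frame(age = c(50, 52, 54, 56),
                                          modality = "fit")),
    U70 = list(age = 70, pre = NULL),
    C70 = list(age = 70, pre = data.frame(age = c(50, 60),
                                          modality = "colonoscopy")),
    F70 = list(age = 70, pre = data.frame(age = 50:69, modality = "fit")))
  if (!code %in% names(defs)) stop("unknown cohort code: ", code)
  d <- defs[[code]]
  pre <- if (is.null(d$pre)) empty_schedule() else d$pre
  structure(list(code = code, age_2020 = d$age,
                 birth_year = 2020.25 - d$age,
                 pre_pandemic_exams = pre),
            class = "crc_cohort")
}

empty_schedule <- function() {
  data.frame(age = numeric(), modality = character(),
             stringsAsFactors = FALSE)
}

#' Disruption specification
#'
#' @param type one of "none", "short_delay", "long_delay_to_age",
#'   "switch_to_fit", "discontinue".
#' @param delay_months 3, 9 or 18 for short delays (and for the delay that
#'   accompanies a switch to FIT).
#' @param resume_age 65 or 75 for long-term delays.
#' @return object of class `crc_disruption`.
#' @export
disruption <- function(type = c("none", "short_delay", "long_delay_to_age",
                                "switch_to_fit", "discontinue"),
                       delay_months = NA_real_, resume_age = NA_real_) {
  type <- match.arg(type)
  if (type %in% c("short_delay", "switch_to_fit") &&
      !delay_months %in% c(3, 9, 18))
    stop("short-term delays are 3, 9 or 18 months")
  if (type == "long_delay_to_age" && !resume_age %in% c(65, 75))
    stop("long-term delays resume at age 65 or 75")
  structure(list(type = type, delay_months = delay_months,
                 resume_age = resume_age),
            class = "crc_disruption")
}

#' Build the no-disruption exam schedule for a cohort
#'
#' Concatenates the cohort's pre-pandemic exams with the counterfactual
#' post-pandemic regimen: decennial colonoscopy to age 70 or annual FIT to
#' age 75, with the first post-pandemic exam due at pandemic onset.
#' Delayed-initiation cohorts (U60, U70) begin late and get no screening
#' beyond the usual stopping age (U70's colonoscopy arm is a single exam at
#' 70).
#'
#' @param cohort a [cohort_spec()].
#' @param modality counterfactual modality, "colonoscopy" or "fit".
#' @return data.frame (`age`, `modality`, `phase` pre/post), chronological.
#' @export
build_counterfactual_schedule <- function(cohort,
                                          modality = c("colonoscopy", "fit")) {
  modality <- match.arg(modality)
  a0 <- cohort$age_2020
  post_ages <- if (modality == "colonoscopy") seq(a0, 70, by = 10)
               else seq(a0, 75, by = 1)
  if (cohort$code %in% c("F60", "f60", "F70") && modality == "colonoscopy")
    stop("cohort ", cohort$code, " has no colonoscopy counterfactual")
  if (cohort$code %in% c("C60", "C70") && modality == "fit")
    stop("cohort ", cohort$code, "'s FIT arm is a switch scenario, ",
         "not a counterfactual")
  pre <- cohort$pre_pandemic_exams
  sched <- rbind(
    if (nrow(pre)) data.frame(age = pre$age, modality = pre$modality,
                              phase = "pre", stringsAsFactors = FALSE),
    data.frame(age = post_ages, modality = modality, phase = "post",
               stringsAsFactors = FALSE))
  sched[order(sched$age), , drop = FALSE]
}

#' Apply a pandemic disruption to a planned schedule
#'
#' Short delays shift the first post-pandemic exam and carry the shift
#' forward to all later planned exams (pairwise gaps are preserved, even
#' past the nominal stopping age). Long-term delays replace the
#' post-pandemic colonoscopies with explicit exams at the resume age (65
#' and 75, or 75 alone for 70-year-olds). Switching to FIT replaces all
#' post-pandemic exams with annual FIT to age 75, shifted by the stated
#' short delay; the switch is permanent. Discontinuation removes every
#' post-pandemic exam.
#'
#' @param schedule a [build_counterfactual_schedule()] data.frame.
#' @param disr a [disruption()].
#' @param pandemic_age the cohort's age at pandemic onset.
#' @return disrupted schedule in the same format.
#' @export
apply_disruption <- function(schedule, disr, pandemic_age) {
  pre <- schedule[schedule$phase == "pre", , drop = FALSE]
  post <- schedule[schedule$phase == "post", , drop = FALSE]
  shift <- function(df, years) { df$age <- df$age + years; df }
  post2 <- switch(disr$type,
    none = post,
    short_delay = shift(post, disr$delay_months / 12),
    long_delay_to_age = {
      ages <- if (pandemic_age >= 70) 75 else c(disr$resume_age, 75)
      data.frame(age = ages, modality = "colonoscopy", phase = "post",
                 stringsAsFactors = FALSE)
    },
    switch_to_fit = {
      base <- data.frame(age = seq(pandemic_age, 75, by = 1),
                         modality = "fit", phase = "post",
                         stringsAsFactors = FALSE)
      shift(base, disr$delay_months / 12)
    },
    discontinue = post[0, , drop = FALSE])
  out <- rbind(pre, post2)
  out[order(out$age), , drop = FALSE]
}

# combinations defined by the study's scenario table
valid_disruptions <- function(code) {
  switch(code,
    U50 = , U60 = c("C[d]m", "C@65", "F[d]m"),
    U70 = c("C[d]m", "C@75", "F[d]m"),
    C60 = c("C[d]m", "F[d]m", "C@65", "U"),
    C70 = c("C[d]m", "F[d]m", "C@75", "U"),
    F60 = , f60 = , F70 = c("F[d]m", "U"))
}

#' Parse a scenario code
#'
#' Scenario labels follow the grammar
#' `"[cohort] | [disruption]"`: `C[d]m` / `F[d]m` are short delays of d
#' months (3, 9 or 18) on the colonoscopy / FIT arm (for the
#' colonoscopy-adherent cohorts C60 and C70, `F[d]m` means a permanent
#' switch to annual FIT with that delay), `C@65` / `C@75` are long-term
#' delays, and `U` is screening discontinuation.
#'
#' @param label scenario label, e.g. `"C60 | F18m"`.
#' @return object of class `crc_scenario` with fields `cohort`,
#'   `modality` (counterfactual modality), `disruption`, `label`.
#' @export
parse_scenario_code <- function(label) {
  m <- regmatches(label, regexec("^\\s*([UCFf]\\d{2})\\s*\\|\\s*(\\S+)\\s*$",
                                 label))[[1]]
  if (length(m) != 3)
    stop("malformed scenario label '", label, "'; expected ",
         "\"<cohort> | <disruption>\" with disruption one of ",
         "C[d]m, F[d]m, C@65, C@75, U (d in 3/9/18)")
  code <- m[2]
  ds <- m[3]
  cohort <- cohort_spec(code)
  fit_is_switch <- code %in% c("C60", "C70")
  if (grepl("^C(3|9|18)m$", ds)) {
    d <- as.numeric(sub("^C(\\d+)m$", "\\1", ds))
    modality <- "colonoscopy"
    disr <- disruption("short_delay", delay_months = d)
    key <- "C[d]m"
  } else if (grepl("^F(3|9|18)m$", ds)) {
    d <- as.numeric(sub("^F(\\d+)m$", "\\1", ds))
    if (fit_is_switch) {
      modality <- "colonoscopy"
      disr <- disruption("switch_to_fit", delay_months = d)
    } else {
      modality <- "fit"
      disr <- disruption("short_delay", delay_months = d)
    }
    key <- "F[d]m"
  } else if (grepl("^C@(65|75)$", ds)) {
    modality <- "colonoscopy"
    disr <- disruption("long_delay_to_age",
                       resume_age = as.numeric(sub("^C@", "", ds)))
    key <- paste0("C@", disr$resume_age)
  } else if (ds == "U") {
    modality <- if (code %in% c("C60", "C70")) "colonoscopy" else "fit"
    disr <- disruption("discontinue")
    key <- "U"
  } else {
    stop("unknown disruption '", ds, "' in scenario label '", label, "'")
  }
  if (!key %in% valid_disruptions(code))
    stop("disruption '", ds, "' is not defined for cohort ", code)
  structure(list(cohort = cohort, modality = modality, disruption = disr,
                 label = render_scenario_code(code, modality, disr)),
            class = "crc_scenario")
}

#' Render a scenario back to its label
#'
#' Inverse of [parse_scenario_code()] on the study's label set.
#'
#' @param code cohort code.
#' @param modality counterfactual modality.
#' @param disr a [disruption()].
#' @return the scenario label string.
#' @export
render_scenario_code <- function(code, modality, disr) {
  ds <- switch(disr$type,
    short_delay = paste0(if (modality == "colonoscopy") "C" else "F",
                         disr$delay_months, "m"),
    switch_to_fit = paste0("F", disr$delay_months, "m"),
    long_delay_to_age = paste0("C@", disr$resume_age),
    discontinue = "U",
    none = "ND")
  paste0(code, " | ", ds)
}

#' @rdname parse_scenario_code
#' @param scenario a `crc_scenario`.
#' @export
scenario_label <- function(scenario) scenario$label

#' All scenario labels defined by the study design
#'
#' @return character vector of concrete labels (short delays expanded to
#'   3, 9, 18 months).
#' @export
scenario_labels <- function() {
  codes <- c("U50", "U60", "C60", "F60", "f60", "U70", "C70", "F70")
  out <- character()
  for (code in codes) {
    for (key in valid_disruptions(code)) {
      out <- c(out, switch(key,
        "C[d]m" = paste0(code, " | C", c(3, 9, 18), "m"),
        "F[d]m" = paste0(code, " | F", c(3, 9, 18), "m"),
        "C@65" = paste0(code, " | C@65"),
        "C@75" = paste0(code, " | C@75"),
        "U" = paste0(code, " | U")))
    }
  }
  out
}

#' @export
print.crc_scenario <- function(x, ...) {
  cat("<crc_scenario>", x$label, "\n")
  cat("  cohort", x$cohort$code, "(age", x$cohort$age_2020, "in April 2020),",
      "counterfactual modality:", x$modality, "\n")
  cat("  disruption:", x$disruption$type,
      if (x$disruption$type %in% c("short_delay", "switch_to_fit"))
        paste0("(", x$disruption$delay_months, " months)"),
      if (x$disruption$type == "long_delay_to_age")
        paste0("(resume at ", x$disruption$resume_age, ")"), "\n")
  invisible(x)
}
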