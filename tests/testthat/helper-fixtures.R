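# Shared in-code fixtures for the test suite.

# a small, fast preset with adjustable pieces; defaults give a simple
# constant onset hazard with no frailty
toy_preset <- function(label = "toy",
                       base_hazard = c(0, 0.02),
                       age_breaks = c(0, 20, 100),
                       frailty_var = 0,
                       transform = list(small = 0.001, medium = 0.005,
                                        large = 0.03),
                       growth_meanlog = -2.0, growth_sdlog = 0.4,
                       sojourn = list(dist = "lognormal", meanlog = 1.0,
                                      sdlog = 0.4),
                       clin_meanlog = log(5), screen_meanlog = log(12),
                       surv_sdlog = 1.0,
                       fit_mode = "per_person") {
  crc_preset(
    label = label,
    adenoma_onset = list(age_breaks = age_breaks,
                         base_hazard = base_hazard,
                         frailty_dist = "gamma", frailty_var = frailty_var,
                         max_lesions = 60),
    growth = list(rate_meanlog = growth_meanlog,
                  rate_sdlog = growth_sdlog, reach_prob = 1.0),
    transformation = transform,
    sojourn = sojourn,
    crc_survival = list(clin_meanlog = clin_meanlog,
                        screen_meanlog = screen_meanlog,
                        sdlog = surv_sdlog),
    fit = list(mode = fit_mode,
               sens = list(small = 0.05, medium = 0.15, large = 0.22),
               sens_preclinical = c(0.74, 0.74), specificity = 0.97))
}

# a hand-built life history: one person, explicit lesions, no spontaneous
# cancer unless transform_age is set
synthetic_history <- function(onset_age = 40, t6 = 5, t10 = 9,
                              transform_age = Inf, sojourn = 3,
                              death_age = 100, n = length(onset_age)) {
  rep_len2 <- function(x) rep_len(x, n)
  structure(list(
    person_id = 1, birth_year = 1970, preset_label = "synthetic",
    frailty = 1,
    adenomas = data.frame(onset_age = rep_len2(onset_age),
                          t6 = rep_len2(t6), t10 = rep_len2(t10),
                          transform_age = rep_len2(transform_age),
                          sojourn = rep_len2(sojourn),
                          clinical_age = rep_len2(transform_age) +
                            rep_len2(sojourn),
                          surv_u = rep_len2(0.5),
                          within_reach = rep_len2(TRUE)),
    other_cause_death_age = death_age,
    clinical_dx_age = NA_real_, crc_death_age = NA_real_,
    death_age = death_age, cause = "other"),
    class = "crc_life_history")
}

# independently hand-coded copy of the surveillance guideline table, used
# as the oracle for exhaustive equivalence checks
oracle_surveillance <- function(second, first) {
  firsts <- c(normal = NA, adenoma_1_2_small = 7, adenoma_3_4_small = 3,
              adenoma_5_10_small_or_any_large = 3, adenoma_gt10 = 1)
  if (first != "normal") {
    if (second %in% c("adenoma_5_10_small_or_any_large", "adenoma_gt10") &&
        first == "adenoma_1_2_small") return(5)
    return(unname(firsts[first]))
  }
  switch(second,
         no_prior = NA,  # resume screening, not an interval
         normal = 10, adenoma_1_2_small = 10, adenoma_3_4_small = 10,
         adenoma_5_10_small_or_any_large = 5, adenoma_gt10 = 5)
}
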