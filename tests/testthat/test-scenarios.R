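test_that("counterfactual schedules match the cohort definitions", {
  f60 <- build_counterfactual_schedule(cohort_spec("F60"), "fit")
  expect_equal(f60$age, c(50:59, 60:75))
  expect_true(all(f60$modality == "fit"))
  expect_equal(f60$phase, c(rep("pre", 10), rep("post", 16)))

  u70 <- build_counterfactual_schedule(cohort_spec("U70"), "colonoscopy")
  expect_equal(u70$age, 70)  # single exam at 70, none past the stop age

  f60b <- build_counterfactual_schedule(cohort_spec("f60"), "fit")
  expect_equal(f60b$age, c(50, 52, 54, 56, 60:75))

  u50 <- build_counterfactual_schedule(cohort_spec("U50"), "colonoscopy")
  expect_equal(u50$age, c(50, 60, 70))
  c70 <- build_counterfactual_schedule(cohort_spec("C70"), "colonoscopy")
  expect_equal(c70$age, c(50, 60, 70))
  expect_equal(c70$phase, c("pre", "pre", "post"))

  expect_error(build_counterfactual_schedule(cohort_spec("F60"),
                                             "colonoscopy"), "counterfactual")
  expect_error(cohort_spec("X50"), "unknown cohort")
})

test_that("disruptions transform schedules as specified", {
  c60 <- build_counterfactual_schedule(cohort_spec("C60"), "colonoscopy")
  # 18-month delay: carried forward, colonoscopies at 61.5 and 71.5
  d <- apply_disruption(c60, disruption("short_delay", 18), 60)
  expect_equal(d$age, c(50, 61.5, 71.5))
  # pairwise gaps between post-pandemic exams are preserved
  post0 <- c60$age[c60$phase == "post"]
  post1 <- d$age[d$phase == "post"]
  expect_equal(diff(post1), diff(post0))

  # discontinuation empties the post-pandemic schedule
  u <- apply_disruption(c60, disruption("discontinue"), 60)
  expect_equal(u$age, 50)

  # long-term delay to 65: colonoscopies at 65 and 75 only
  u50 <- build_counterfactual_schedule(cohort_spec("U50"), "colonoscopy")
  ld <- apply_disruption(u50, disruption("long_delay_to_age",
                                         resume_age = 65), 50)
  expect_equal(ld$age, c(65, 75))
  # 70-year-olds resume at 75 with a single exam
  u70 <- build_counterfactual_schedule(cohort_spec("U70"), "colonoscopy")
  ld75 <- apply_disruption(u70, disruption("long_delay_to_age",
                                           resume_age = 75), 70)
  expect_equal(ld75$age, 75)

  # switching to FIT: annual FIT to 75 shifted by the delay, permanent
  sw <- apply_disruption(c60, disruption("switch_to_fit", 18), 60)
  expect_equal(sw$age, c(50, 60:75 + 1.5))
  expect_equal(sw$modality, c("colonoscopy", rep("fit", 16)))
})

test_that("scenario labels parse and round-trip over the whole study grid", {
  labs <- scenario_labels()
  expect_length(labs, 49)  # 8 cohorts x their defined disruption sets
  for (lab in labs) {
    sc <- parse_scenario_code(lab)
    expect_equal(sc$label, lab)
  }
  sc <- parse_scenario_code("C60 | F18m")
  expect_equal(sc$cohort$code, "C60")
  expect_equal(sc$disruption$type, "switch_to_fit")
  expect_equal(sc$disruption$delay_months, 18)
  sc2 <- parse_scenario_code("F70 | U")
  expect_equal(sc2$disruption$type, "discontinue")
  sc3 <- parse_scenario_code("U70 | C@75")
  expect_equal(sc3$disruption$resume_age, 75)
  # F[d]m on a FIT cohort is a plain delay, not a switch
  sc4 <- parse_scenario_code("F60 | F9m")
  expect_equal(sc4$disruption$type, "short_delay")

  expect_error(parse_scenario_code("C60|X"), "malformed|unknown")
  expect_error(parse_scenario_code("F60 | C3m"), "not defined")
  expect_error(parse_scenario_code("U50 | U"), "not defined")
  expect_error(parse_scenario_code("C60 | F6m"), "unknown|not defined")
})

test_that("scenario runs respect the common-random-numbers identities", {
  p <- default_presets()[["preset-A"]]
  lt <- make_life_table()
  pop <- generate_population(p, lt, n = 3000, seed = 31)

  # zero test sensitivity: screening can have no effect, person by person
  zero_colo <- test_profile("colonoscopy", 0, 0, 0, 0, 0.86)
  zero_fit <- test_profile("fit", 0, 0, 0, 0, 0.97,
                           positivity_mode = "per_person")
  sched <- build_counterfactual_schedule(cohort_spec("U50"), "colonoscopy")
  scr <- run_schedule(pop, sched, p, colo_profile = zero_colo,
                      fit_profile = zero_fit)
  uns <- unscreened_outcomes(pop, p)
  expect_identical(scr$death_age, uns$death_age)
  expect_identical(scr$dx_age, uns$dx_age)

  # no disruption reproduces the counterfactual bit for bit
  cf <- build_counterfactual_schedule(cohort_spec("C60"), "colonoscopy")
  nd1 <- run_schedule(pop, cf, p, pandemic_age = 60)
  nd2 <- run_schedule(pop, apply_disruption(cf, disruption("none"), 60),
                      p, pandemic_age = 60)
  expect_identical(nd1, nd2)

  # the natural history consumed by different scenarios is the same object
  expect_identical(population_digest(pop),
                   population_digest(generate_population(p, lt, 1970,
                                                         3000, 31)))
})

test_that("longer delays cost life-years in expectation", {
  p <- default_presets()[["preset-A"]]
  r3 <- run_scenario("U50 | C3m", preset = p, n = 30000, seed = 41)
  r18 <- run_scenario("U50 | C18m", preset = p, n = 30000, seed = 41)
  d3 <- r3$outcomes$LYL
  d18 <- r18$outcomes$LYL
  se <- sqrt(r3$outcomes$mc_se["LYL"]^2 + r18$outcomes$mc_se["LYL"]^2)
  expect_gt(d18 - d3, -3 * se)
})
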