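lt <- make_life_table()

test_that("degenerate hazards produce degenerate histories", {
  # zero onset hazard: no adenomas, no CRC, death at the other-cause age
  p0 <- toy_preset(base_hazard = c(0, 0))
  pop <- generate_population(p0, lt, n = 200, seed = 1)
  expect_true(all(pop$n_lesions == 0))
  u <- unscreened_outcomes(pop, p0)
  expect_true(all(is.na(u$dx_age)))
  expect_equal(u$death_age, pop$oc_death_age)

  # zero transformation: adenomas occur but never become cancer
  pt <- toy_preset(transform = list(small = 0, medium = 0, large = 0))
  popt <- generate_population(pt, lt, n = 500, seed = 2)
  expect_gt(sum(popt$n_lesions), 0)
  ut <- unscreened_outcomes(popt, pt)
  expect_true(all(is.na(ut$dx_age)))
})

test_that("constant onset hazard with zero frailty is homogeneous Poisson", {
  # fraction with >= 1 adenoma by age a is 1 - exp(-lambda * a)
  lam <- 0.02
  a <- 60
  p <- toy_preset(base_hazard = c(lam, lam), age_breaks = c(0, 20, 100),
                  frailty_var = 0,
                  transform = list(small = 0, medium = 0, large = 0))
  lt_im <- make_life_table(0, 0, 0.1)  # no deaths before the horizon
  pop <- generate_population(p, lt_im, n = 1e5, seed = 7)
  ptr <- c(0, cumsum(pop$n_lesions))
  has_by_a <- vapply(seq_len(pop$n), function(i) {
    j <- if (ptr[i + 1] > ptr[i]) (ptr[i] + 1):ptr[i + 1] else integer()
    any(pop$onset_age[j] <= a)
  }, logical(1))
  phat <- mean(has_by_a)
  p_true <- 1 - exp(-lam * a)
  expect_lt(abs(phat - p_true), 3 * sqrt(p_true * (1 - p_true) / 1e5))
})

test_that("lesion size class grows monotonically through the thresholds", {
  ad <- list(onset_age = 40, t6 = 5, t10 = 9)
  expect_equal(lesion_size_class(ad, 40), "1-5mm")  # lesions start small
  expect_equal(lesion_size_class(ad, 44.999), "1-5mm")
  expect_equal(lesion_size_class(ad, 45.001), "6-9mm")
  expect_equal(lesion_size_class(ad, 48.999), "6-9mm")
  expect_equal(lesion_size_class(ad, 49.001), ">=10mm")
  expect_error(lesion_size_class(ad, 39), "onset")

  # zero growth rate (infinite thresholds): small at all ages
  ad0 <- list(onset_age = 40, t6 = Inf, t10 = Inf)
  expect_equal(lesion_size_class(ad0, 99), "1-5mm")

  cls <- lesion_size_class(ad, seq(40, 60, by = 0.25))
  ord <- match(cls, c("1-5mm", "6-9mm", ">=10mm"))
  expect_true(all(diff(ord) >= 0))
})

test_that("CRC survival sampling has the configured distribution", {
  p <- toy_preset()
  # degenerate quantile checks: same u, screen-detected never earlier
  u <- seq(0.05, 0.95, by = 0.1)
  clin <- crc_death_age(p, 60, "clinical", u)
  scr <- crc_death_age(p, 60, "screen", u)
  expect_true(all(scr >= clin))
  expect_true(all(clin > 60))
  # moment check against the lognormal mean
  uu <- rng_uniforms(1, 1, 9, 0:99999)
  m <- mean(crc_death_age(p, 0, "clinical", uu))
  expect_equal(m, exp(log(5) + 0.5), tolerance = 0.02)
})

test_that("event ordering holds for every person with cancer", {
  p <- default_presets()[["preset-A"]]
  pop <- generate_population(p, lt, n = 5000, seed = 13)
  u <- unscreened_outcomes(pop, p)
  ptr <- c(0, cumsum(pop$n_lesions))
  for (i in which(!is.na(u$dx_age))) {
    j <- (ptr[i] + 1):ptr[i + 1]
    culprit <- j[which.min(pop$clinical_age[j])]
    expect_gt(pop$transform_age[culprit], pop$onset_age[culprit])
    expect_gt(pop$clinical_age[culprit], pop$transform_age[culprit])
    expect_gt(u$crc_death_age[i], u$dx_age[i])
  }
  expect_true(all(u$death_age <= pop$oc_death_age + 1e-12))
})

test_that("with no adenomas mean life-years match the life table", {
  p0 <- toy_preset(base_hazard = c(0, 0))
  pop <- generate_population(p0, lt, n = 4e4, seed = 17)
  u <- unscreened_outcomes(pop, p0)
  m <- mean(u$death_age)
  se <- stats::sd(u$death_age) / sqrt(pop$n)
  expect_lt(abs(m - life_table_expectation(lt, 0)), 3 * se)
})

test_that("populations are deterministic and prefix-stable", {
  p <- default_presets()[["preset-B"]]
  a <- generate_population(p, lt, n = 300, seed = 99)
  b <- generate_population(p, lt, n = 300, seed = 99)
  expect_identical(population_digest(a), population_digest(b))
  expect_identical(a$onset_age, b$onset_age)

  # the first k persons of a larger run equal the k-person run
  big <- generate_population(p, lt, n = 600, seed = 99)
  k <- 300
  expect_identical(big$oc_death_age[1:k], a$oc_death_age)
  expect_identical(big$n_lesions[1:k], a$n_lesions)
  nles <- sum(a$n_lesions)
  expect_identical(big$onset_age[1:nles], a$onset_age)

  # different seeds give different digests
  c2 <- generate_population(p, lt, n = 300, seed = 100)
  expect_false(population_digest(c2) == population_digest(a))
})

test_that("single-person histories are consistent with the population view", {
  p <- default_presets()[["preset-A"]]
  h <- simulate_life_history(p, lt, person_id = 4, seed = 21)
  pop <- generate_population(p, lt, n = 10, seed = 21)
  expect_equal(nrow(h$adenomas), pop$n_lesions[4])
  expect_equal(h$other_cause_death_age, pop$oc_death_age[4])
  df <- as.data.frame(pop)
  expect_equal(df$death_age[4], h$death_age)
  expect_equal(nrow(df), 10)
})

test_that("invalid preset parameters are rejected", {
  expect_error(toy_preset(base_hazard = c(-0.1, 0)), "non-negative")
  expect_error(toy_preset(transform = list(small = 1.2, medium = 0,
                                           large = 0)), "probabilit")
  expect_error(toy_preset(clin_meanlog = 3, screen_meanlog = 1),
               "dominate")
})
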