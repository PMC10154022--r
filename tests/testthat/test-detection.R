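profiles <- default_test_profiles()

test_that("bundled profiles reproduce the assumed test characteristics", {
  hi <- profiles$colonoscopy_high
  lo <- profiles$colonoscopy_low
  expect_equal(c(hi$sens_small, hi$sens_medium, hi$sens_large,
                 hi$sens_preclinical[1], hi$specificity),
               c(0.75, 0.85, 0.95, 0.95, 0.86))
  expect_equal(c(lo$sens_small, lo$sens_medium, lo$sens_large,
                 lo$sens_preclinical[1], lo$specificity),
               c(0.55, 0.70, 0.90, 0.95, 0.86))
  pp <- profiles$fit_per_person
  pl <- profiles$fit_per_lesion
  expect_equal(c(pp$sens_small, pp$sens_medium, pp$sens_large,
                 pp$sens_preclinical, pp$specificity),
               c(0.05, 0.15, 0.22, 0.74, 0.74, 0.97))
  expect_equal(c(pl$sens_small, pl$sens_medium, pl$sens_large,
                 pl$sens_preclinical, pl$specificity),
               c(0.00, 0.114, 0.159, 0.62565, 0.886, 0.97))
  # high-sensitivity colonoscopy dominates low component-wise
  expect_true(all(c(hi$sens_small, hi$sens_medium, hi$sens_large) >=
                  c(lo$sens_small, lo$sens_medium, lo$sens_large)))
  # constructor enforces monotonicity in size class
  expect_error(test_profile("colonoscopy", 0.9, 0.8, 0.95, 0.95, 0.86),
               "non-decreasing")
})

test_that("colonoscopy detects each prevalent lesion with its size sensitivity", {
  # perfect sensitivity detects everything prevalent
  perfect <- test_profile("colonoscopy", 1, 1, 1, 1, 0.86)
  h <- synthetic_history(onset_age = c(30, 40, 50), t6 = 5, t10 = 9)
  res <- colonoscopy_exam(h, 60, perfect, crc_rng(1))
  expect_equal(res$detected_adenomas, 1:3)

  # a lesion not yet prevalent cannot be detected
  res2 <- colonoscopy_exam(h, 45, perfect, crc_rng(1))
  expect_equal(res2$detected_adenomas, 1:2)

  # one >= 10 mm lesion: detection frequency ~ 0.95 (high profile)
  h1 <- synthetic_history(onset_age = 40, t6 = 2, t10 = 4)
  n <- 2e4
  rng <- crc_rng(5)
  hits <- vapply(seq_len(n), function(k)
    length(colonoscopy_exam(h1, 60, profiles$colonoscopy_high,
                            rng)$detected_adenomas) > 0, logical(1))
  expect_lt(abs(mean(hits) - 0.95), 3 * sqrt(0.95 * 0.05 / n))

  # one small + one medium lesion: P(>= 1 detected) = 1-(1-.75)(1-.85)
  h2 <- synthetic_history(onset_age = c(58, 50), t6 = c(50, 8),
                          t10 = c(99, 99))
  rng2 <- crc_rng(6)
  hits2 <- vapply(seq_len(n), function(k)
    length(colonoscopy_exam(h2, 60, profiles$colonoscopy_high,
                            rng2)$detected_adenomas) > 0, logical(1))
  p2 <- 1 - (1 - 0.75) * (1 - 0.85)
  expect_lt(abs(mean(hits2) - p2), 3 * sqrt(p2 * (1 - p2) / n))

  # out-of-reach lesions are never detected
  h3 <- synthetic_history(onset_age = 40)
  h3$adenomas$within_reach <- FALSE
  res3 <- colonoscopy_exam(h3, 60, perfect, crc_rng(1))
  expect_length(res3$detected_adenomas, 0)

  expect_error(colonoscopy_exam(synthetic_history(death_age = 55), 60,
                                perfect, crc_rng(1)), "death")
})

test_that("FIT positivity follows the per-person and per-lesion models", {
  n <- 2e4
  # lesion-free person: positive with 1 - specificity = 0.03
  h0 <- synthetic_history(onset_age = numeric(0), n = 0)
  for (prof in profiles[c("fit_per_person", "fit_per_lesion")]) {
    rng <- crc_rng(11)
    pos <- vapply(seq_len(n), function(k)
      fit_exam(h0, 60, prof, rng)$positive, logical(1))
    expect_lt(abs(mean(pos) - 0.03), 3 * sqrt(0.03 * 0.97 / n))
  }

  # per-person: most advanced lesion >= 10 mm gives 0.22
  h1 <- synthetic_history(onset_age = c(40, 55), t6 = c(2, 50),
                          t10 = c(4, 99))
  rng <- crc_rng(12)
  pos1 <- vapply(seq_len(n), function(k)
    fit_exam(h1, 60, profiles$fit_per_person, rng)$positive, logical(1))
  expect_lt(abs(mean(pos1) - 0.22), 3 * sqrt(0.22 * 0.78 / n))

  # per-lesion with two 6-9 mm adenomas, specificity channel disabled:
  # P = 1 - (1 - 0.114)^2 = 0.214604
  prof_nospec <- test_profile("fit", 0, 0.114, 0.159, c(0.62565, 0.886),
                              specificity = 1, positivity_mode = "per_lesion")
  h2 <- synthetic_history(onset_age = c(50, 52), t6 = 2, t10 = 99)
  rng <- crc_rng(13)
  pos2 <- vapply(seq_len(n), function(k)
    fit_exam(h2, 60, prof_nospec, rng)$positive, logical(1))
  p2 <- 1 - (1 - 0.114)^2
  expect_lt(abs(mean(pos2) - p2), 4 * sqrt(p2 * (1 - p2) / n))
  # and combined with the bleeding channel analytically
  rng <- crc_rng(13)
  pos3 <- vapply(seq_len(n), function(k)
    fit_exam(h2, 60, profiles$fit_per_lesion, rng)$positive, logical(1))
  p3 <- 1 - (1 - p2) * 0.97
  expect_lt(abs(mean(pos3) - p3), 4 * sqrt(p3 * (1 - p3) / n))

  # per-lesion small-adenoma sensitivity 0 means smalls never trigger FIT
  h4 <- synthetic_history(onset_age = 59, t6 = 50, t10 = 99)
  rng <- crc_rng(14)
  pos4 <- vapply(seq_len(5000), function(k)
    fit_exam(h4, 60, prof_nospec, rng)$positive, logical(1))
  expect_false(any(pos4))
})

test_that("detection is monotone in size class and across profiles", {
  n <- 1e4
  # detection frequency non-decreasing in size class, both profiles
  for (prof in profiles[c("colonoscopy_high", "colonoscopy_low")]) {
    freq <- vapply(list(c(50, 99), c(5, 99), c(2, 4)), function(th) {
      h <- synthetic_history(onset_age = 40, t6 = th[1], t10 = th[2])
      rng <- crc_rng(20)
      mean(vapply(seq_len(n), function(k)
        length(colonoscopy_exam(h, 60, prof, rng)$detected_adenomas) > 0,
        logical(1)))
    }, numeric(1))
    expect_true(all(diff(freq) > 0))
  }

  # shared uniforms: lesions detected under the low profile are a subset
  # of those detected under the high profile
  h <- synthetic_history(onset_age = c(30, 35, 40, 45, 50),
                         t6 = c(2, 5, 10, 40, 80), t10 = c(4, 9, 20, 80, 99))
  for (k in 1:200) {
    rh <- crc_rng(k); rl <- crc_rng(k)
    dh <- colonoscopy_exam(h, 60, profiles$colonoscopy_high, rh)$detected_adenomas
    dl <- colonoscopy_exam(h, 60, profiles$colonoscopy_low, rl)$detected_adenomas
    expect_true(all(dl %in% dh))
  }
})

test_that("diagnostic colonoscopy follows a positive FIT", {
  perfect <- test_profile("colonoscopy", 1, 1, 1, 1, 0.86)
  h <- synthetic_history(onset_age = 40, t6 = 2, t10 = 4)
  rng <- crc_rng(30)
  ft <- fit_exam(h, 60, profiles$fit_per_person, rng)
  if (ft$positive) {
    dg <- diagnostic_colonoscopy_after_positive_fit(h, 60, ft, perfect, rng)
    expect_equal(dg$exam_kind, "diagnostic")
    expect_equal(dg$detected_adenomas, 1L)
  }
  neg <- ft; neg$positive <- FALSE
  expect_error(diagnostic_colonoscopy_after_positive_fit(h, 60, neg,
                                                         perfect, rng),
               "positive")
  # preclinical cancer present: detection ends screening with screen mode
  hc <- synthetic_history(onset_age = 40, t6 = 2, t10 = 4,
                          transform_age = 55, sojourn = 10)
  res <- colonoscopy_exam(hc, 60, perfect, crc_rng(2))
  expect_true(res$detected_cancer)
  expect_length(res$detected_adenomas, 0)
})
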