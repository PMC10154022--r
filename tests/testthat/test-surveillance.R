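tbl <- surveillance_table()

test_that("findings classification matches the guideline categories", {
  mk <- function(ns, nl, cancer = FALSE)
    list(modality = "colonoscopy", n_small = ns, n_large = nl,
         detected_cancer = cancer)
  expect_equal(classify_findings(mk(0, 0)), "normal")
  expect_equal(classify_findings(mk(2, 0)), "adenoma_1_2_small")
  expect_equal(classify_findings(mk(3, 0)), "adenoma_3_4_small")
  expect_equal(classify_findings(mk(0, 1)), "adenoma_5_10_small_or_any_large")
  expect_equal(classify_findings(mk(5, 0)), "adenoma_5_10_small_or_any_large")
  expect_equal(classify_findings(mk(11, 0)), "adenoma_gt10")
  expect_equal(classify_findings(mk(9, 2)), "adenoma_gt10")
  expect_equal(classify_findings(mk(1, 0, cancer = TRUE)), "crc")
  expect_error(classify_findings(list(modality = "fit", positive = TRUE)),
               "colonoscopy")
})

test_that("surveillance intervals agree with the hand-coded oracle on every pair", {
  seconds <- findings_categories()[1:6]
  firsts <- findings_categories()[2:6]
  for (s in seconds) for (f in firsts) {
    expected <- oracle_surveillance(s, f)
    if (is.na(expected)) {
      expect_error(surveillance_interval(s, f, tbl), "resume|interval")
    } else {
      expect_equal(surveillance_interval(s, f, tbl), expected,
                   info = paste(s, "->", f))
    }
  }
  # spot checks straight from the guideline table
  expect_equal(surveillance_interval("normal", "adenoma_1_2_small", tbl), 7)
  expect_equal(surveillance_interval("adenoma_5_10_small_or_any_large",
                                     "normal", tbl), 5)
  # shortest-interval rule: 3-4 small adenomas get 3 years, not 5
  expect_equal(surveillance_interval("normal", "adenoma_3_4_small", tbl), 3)
  # >10 adenomas always gets 1 year whatever came before
  for (s in seconds)
    expect_equal(surveillance_interval(s, "adenoma_gt10", tbl), 1)
  expect_error(surveillance_interval("normal", "crc", tbl), "CRC")
})

test_that("routine scheduling honours intervals and the 10-year resume rule", {
  fitpol <- screening_policy("fit", 50, 75, 1)
  # last FIT negative at 60: next FIT at 61
  h <- exam_history(age = c(59, 60), modality = c("fit", "fit"),
                    kind = c("screening", "screening"),
                    category = c(NA, NA))
  nx <- next_event(h, fitpol, now = 60)
  expect_equal(nx, list(age = 61, modality = "fit", kind = "screening"))

  # normal diagnostic colonoscopy at 60 under a FIT policy: next exam is
  # FIT at age 70
  h2 <- exam_history(age = c(59, 60, 60),
                     modality = c("fit", "fit", "colonoscopy"),
                     kind = c("screening", "screening", "diagnostic"),
                     category = c(NA, NA, "normal"))
  nx2 <- next_event(h2, fitpol, now = 60)
  expect_equal(nx2$age, 70)
  expect_equal(nx2$modality, "fit")

  # fresh policy starts at start_age
  nx3 <- next_event(exam_history(), fitpol, now = 50)
  expect_equal(nx3$age, 50)

  # routine colonoscopy past the stopping age is dropped
  colpol <- screening_policy("colonoscopy", 50, 70, 10)
  h4 <- exam_history(age = c(50, 60, 70),
                     modality = rep("colonoscopy", 3),
                     kind = rep("screening", 3),
                     category = rep("normal", 3))
  expect_null(next_event(h4, colpol, now = 70))
  expect_equal(apply_stopping_rules(h4, colpol, 80, "screening"), "drop")
})

test_that("surveillance past age 85 follows the worked stopping example", {
  colpol <- screening_policy("colonoscopy", 50, 70, 10)
  # adenomas at 83: surveillance at 90 is scheduled despite the stop age
  h <- exam_history(age = c(73, 83), modality = rep("colonoscopy", 2),
                    kind = c("surveillance", "surveillance"),
                    category = c("normal", "adenoma_1_2_small"))
  nx <- next_event(h, colpol, now = 83)
  expect_equal(nx$age, 90)
  expect_equal(nx$kind, "surveillance")
  expect_equal(apply_stopping_rules(h, colpol, 90, "surveillance"),
               "schedule")

  # negative exams at 83 and before: the age-93 proposal is dropped
  h2 <- exam_history(age = c(73, 83), modality = rep("colonoscopy", 2),
                     kind = c("surveillance", "surveillance"),
                     category = c("adenoma_1_2_small", "normal"))
  expect_equal(apply_stopping_rules(h2, colpol, 93, "surveillance"), "drop")
  expect_null(next_event(h2, colpol, now = 83))

  # within the stopping age surveillance continues after a normal exam
  h3 <- exam_history(age = c(60, 63), modality = rep("colonoscopy", 2),
                     kind = c("screening", "surveillance"),
                     category = c("adenoma_3_4_small", "normal"))
  nx3 <- next_event(h3, colpol, now = 63)
  expect_equal(nx3$age, 73)  # (3-4 small, normal) -> 10 years
})

test_that("bundled surveillance table matches the shipped CSV cell-for-cell", {
  csv <- utils::read.csv(system.file("extdata", "surveillance_intervals.csv",
                                     package = "crcdisrupt"),
                         colClasses = "character")
  expect_equal(nrow(csv), 30)  # 6 second-categories x 5 first-categories
  for (i in seq_len(nrow(csv))) {
    v <- csv$interval_years[i]
    cell <- tbl[csv$second_category[i], csv$first_category[i]]
    if (v == "resume") expect_true(is.na(cell))
    else expect_equal(unname(cell), as.integer(v))
  }
  # every defined interval uses one of the guideline's year values
  expect_true(all(tbl[!is.na(tbl)] %in% c(1, 3, 5, 7, 10)))
})
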