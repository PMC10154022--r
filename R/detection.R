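#' Run a single colonoscopy exam on a life history
#'
#' Every prevalent within-reach adenoma is independently detected with its
#' size-class sensitivity and removed if detected; a prevalent preclinical
#' cancer is detected with the profile's preclinical sensitivity, which
#' ends the screening process with a screen-detected diagnosis. The
#' underlying life history is never mutated: removal is represented by the
#' returned index set, which the caller carries forward within a scenario.
#'
#' @param history a [simulate_life_history()] object.
#' @param age exam age; the person must be alive and undiagnosed.
#' @param profile a colonoscopy [test_profile()].
#' @param rng a [crc_rng()] stream for the person (draws one 64-uniform
#'   exam block: slot 0 person-level, slot `j` for lesion `j`).
#' @param removed integer indices of lesions already removed in this
#'   scenario.
#' @return object of class `crc_exam_result`: `exam_age`, `exam_kind`,
#'   `detected_adenomas` (lesion indices), `n_small`, `n_large`,
#'   `detected_cancer`, `removed` (updated index set).
#' @export
colonoscopy_exam <- function(history, age, profile, rng,
                             removed = integer()) {
  stopifnot(profile$modality == "colonoscopy")
  if (age >= history$death_age)
    stop("exam scheduled after death")
  if (!is.na(history$clinical_dx_age) && age >= history$clinical_dx_age)
    stop("exam scheduled after clinical CRC diagnosis")
  les <- history$adenomas
  u <- rng$exam_block()
  det <- integer(); n_small <- 0L; n_large <- 0L; cancer <- FALSE
  for (j in seq_len(nrow(les))) {
    if (j %in% removed || les$onset_age[j] > age || !les$within_reach[j])
      next
    uj <- u[j + 1]
    if (age < les$transform_age[j]) {
      sc <- lesion_size_class(les[j, ], age)
      s <- switch(sc, "1-5mm" = profile$sens_small,
                  "6-9mm" = profile$sens_medium, profile$sens_large)
      if (uj < s) {
        det <- c(det, j)
        if (sc == ">=10mm") n_large <- n_large + 1L
        else n_small <- n_small + 1L
      }
    } else if (age < les$clinical_age[j]) {
      if (uj < profile$sens_preclinical[1]) cancer <- TRUE
    }
  }
  structure(list(modality = "colonoscopy", exam_age = age,
                 exam_kind = "screening",
                 detected_adenomas = det, n_small = n_small,
                 n_large = n_large, detected_cancer = cancer,
                 removed = sort(unique(c(removed, det)))),
            class = "crc_exam_result")
}

# sensitivity of a lesion for a FIT profile at a given age, with the
# preclinical stage split at the sojourn midpoint
fit_lesion_sensitivity <- function(les, j, age, profile) {
  if (age < les$transform_age[j]) {
    sc <- lesion_size_class(les[j, ], age)
    switch(sc, "1-5mm" = profile$sens_small,
           "6-9mm" = profile$sens_medium, profile$sens_large)
  } else if (age - les$transform_age[j] < 0.5 * les$sojourn[j]) {
    profile$sens_preclinical[1]
  } else {
    profile$sens_preclinical[2]
  }
}

#' Run a single FIT exam on a life history
#'
#' Under per-person positivity the test is positive with the sensitivity
#' of the most advanced prevalent lesion (preclinical cancer > large >
#' medium > small), or with 1 - specificity if no lesion is present. Under
#' per-lesion positivity each prevalent lesion triggers its own Bernoulli
#' draw and an independent other-cause-bleeding draw fires with
#' 1 - specificity regardless of adenoma status.
#'
#' @inheritParams colonoscopy_exam
#' @param profile a FIT [test_profile()].
#' @return a `crc_exam_result` with field `positive`.
#' @export
fit_exam <- function(history, age, profile, rng, removed = integer()) {
  stopifnot(profile$modality == "fit")
  if (age >= history$death_age) stop("exam scheduled after death")
  les <- history$adenomas
  u <- rng$exam_block()
  prev <- setdiff(which(les$onset_age <= age), removed)
  prev <- prev[is.na(les$clinical_age[prev]) | age < les$clinical_age[prev]]
  if (profile$positivity_mode == "per_lesion") {
    pos <- u[1] < (1 - profile$specificity)
    for (j in prev)
      if (u[j + 1] < fit_lesion_sensitivity(les, j, age, profile))
        pos <- TRUE
  } else {
    s <- 1 - profile$specificity
    best <- -1
    for (j in prev) {
      rnk <- if (age < les$transform_age[j]) {
        match(lesion_size_class(les[j, ], age), c("1-5mm", "6-9mm", ">=10mm")) - 1
      } else if (age - les$transform_age[j] < 0.5 * les$sojourn[j]) 3 else 4
      if (rnk > best) {
        best <- rnk
        s <- fit_lesion_sensitivity(les, j, age, profile)
      }
    }
    pos <- u[1] < s
  }
  structure(list(modality = "fit", exam_age = age, exam_kind = "screening",
                 positive = pos, removed = removed),
            class = "crc_exam_result")
}

#' Diagnostic colonoscopy following a positive FIT
#'
#' Behaves exactly as [colonoscopy_exam()] at the same age, with exam kind
#' `"diagnostic"`; a normal result routes through the 10-year resume rule
#' rather than surveillance.
#'
#' @inheritParams colonoscopy_exam
#' @param fit_result the positive `crc_exam_result` that triggered it.
#' @param colo_profile a colonoscopy [test_profile()].
#' @return a `crc_exam_result`.
#' @export
diagnostic_colonoscopy_after_positive_fit <- function(history, age,
                                                      fit_result,
                                                      colo_profile, rng,
                                                      removed = integer()) {
  if (!isTRUE(fit_result$positive))
    stop("diagnostic colonoscopy requires a positive FIT at the same age")
  if (!isTRUE(all.equal(fit_result$exam_age, age)))
    stop("diagnostic colonoscopy must occur at the FIT age")
  res <- colonoscopy_exam(history, age, colo_profile, rng, removed)
  res$exam_kind <- "diagnostic"
  res
}
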