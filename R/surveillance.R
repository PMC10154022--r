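#' Colonoscopy findings categories
#'
#' The five mutually exclusive findings categories of the surveillance
#' guideline table, plus `no_prior` (no previous colonoscopy) and `crc`
#' (cancer detected, which ends the screening process). "Small" means
#' adenomas under 10 mm.
#'
#' @return character vector of category names.
#' @export
findings_categories <- function() {
  c("no_prior", "normal", "adenoma_1_2_small", "adenoma_3_4_small",
    "adenoma_5_10_small_or_any_large", "adenoma_gt10", "crc")
}

#' The colonoscopy surveillance interval table
#'
#' Mapping from (finding at the second-most recent colonoscopy, finding at
#' the most recent colonoscopy) to the interval, in years, until the next
#' surveillance colonoscopy, following the Multi-Society Task Force
#' guideline with the shortest interval chosen wherever the guideline gives
#' a range. The (no prior, normal) cell is not an interval: a person whose
#' first colonoscopy is normal resumes screening with the original modality
#' 10 years later instead of entering surveillance.
#'
#' @param path optional CSV (columns `second_category`, `first_category`,
#'   `interval_years`) to read instead of the bundled table.
#' @return object of class `crc_surveillance_table`: an integer matrix,
#'   rows = second-most-recent finding (including `no_prior`), columns =
#'   most recent finding; `NA` marks the resume-screening cell.
#' @export
surveillance_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "surveillance_intervals.csv",
                        package = "crcdisrupt", mustWork = TRUE)
  df <- utils::read.csv(path, colClasses = "character")
  secs <- findings_categories()[1:6]
  firsts <- findings_categories()[2:6]
  m <- matrix(NA_integer_, nrow = length(secs), ncol = length(firsts),
              dimnames = list(second = secs, first = firsts))
  for (i in seq_len(nrow(df))) {
    v <- df$interval_years[i]
    m[df$second_category[i], df$first_category[i]] <-
      if (v == "resume") NA_integer_ else as.integer(v)
  }
  structure(m, class = c("crc_surveillance_table", class(m)))
}

#' Classify colonoscopy findings
#'
#' Deterministically maps a colonoscopy result to a findings category:
#' detected cancer dominates; then the count of detected adenomas and
#' whether any is >= 10 mm select among the guideline categories. More than
#' 10 adenomas of any size map to `adenoma_gt10`.
#'
#' @param result a `crc_exam_result` from [colonoscopy_exam()], or a list
#'   with `detected_cancer`, `n_small`, `n_large`.
#' @return a findings category string.
#' @export
classify_findings <- function(result) {
  if (!is.null(result$modality) && result$modality != "colonoscopy")
    stop("findings categories are defined for colonoscopy results only")
  if (isTRUE(result$detected_cancer)) return("crc")
  ns <- result$n_small
  nl <- result$n_large
  n <- ns + nl
  if (n == 0) "normal"
  else if (n > 10) "adenoma_gt10"
  else if (nl > 0 || n >= 5) "adenoma_5_10_small_or_any_large"
  else if (n >= 3) "adenoma_3_4_small"
  else "adenoma_1_2_small"
}

#' Look up a surveillance interval
#'
#' @param second finding at the second-most recent colonoscopy (may be
#'   `"no_prior"`).
#' @param first finding at the most recent colonoscopy.
#' @param table a [surveillance_table()].
#' @return interval in years.
#' @export
surveillance_interval <- function(second, first, table = surveillance_table()) {
  if (first == "crc" || second == "crc")
    stop("no surveillance is scheduled after a CRC diagnosis")
  if (!second %in% rownames(table) || !first %in% colnames(table))
    stop("unknown findings category")
  iv <- table[second, first]
  if (is.na(iv))
    stop("(no prior, normal) has no surveillance interval: ",
         "screening resumes with the original modality after 10 years")
  as.numeric(iv)
}

#' Routine screening policy
#'
#' @param modality "colonoscopy" or "fit".
#' @param start_age,stop_age routine screening window (start < stop).
#' @param interval years between routine exams (10 for colonoscopy, 1 or 2
#'   for FIT).
#' @param surveillance_stop_age age after which surveillance stops following
#'   a negative exam (default 85).
#' @return object of class `crc_policy`.
#' @export
screening_policy <- function(modality = c("colonoscopy", "fit"),
                             start_age = 50, stop_age = if (modality == "colonoscopy") 70 else 75,
                             interval = if (modality == "colonoscopy") 10 else 1,
                             surveillance_stop_age = 85) {
  modality <- match.arg(modality)
  stopifnot(start_age < stop_age, stop_age <= surveillance_stop_age,
            interval > 0)
  structure(list(modality = modality, start_age = start_age,
                 stop_age = stop_age, interval = interval,
                 surveillance_stop_age = surveillance_stop_age),
            class = "crc_policy")
}

#' Exam history container
#'
#' A chronological record of exams for one person: ages, modalities, kinds
#' (screening / diagnostic / surveillance) and, for colonoscopies, findings
#' categories. Used by the pure scheduling functions [next_event()] and
#' [apply_stopping_rules()].
#'
#' @param age,modality,kind,category parallel vectors (possibly empty).
#' @return object of class `crc_exam_history` (a data.frame).
#' @export
exam_history <- function(age = numeric(), modality = character(),
                         kind = character(), category = character()) {
  df <- data.frame(age = age, modality = modality, kind = kind,
                   category = as.character(category),
                   stringsAsFactors = FALSE)
  if (is.unsorted(df$age)) stop("exam history must be chronological")
  if (any(df$category %in% "crc" & seq_len(nrow(df)) < nrow(df)))
    stop("exam history ends at the first CRC diagnosis")
  structure(df, class = c("crc_exam_history", "data.frame"))
}

# findings at the two most recent colonoscopies in a history
last_two_colonoscopy_findings <- function(history) {
  cols <- history[history$modality == "colonoscopy", , drop = FALSE]
  k <- nrow(cols)
  list(first = if (k >= 1) cols$category[k] else "no_prior",
       second = if (k >= 2) cols$category[k - 1] else "no_prior",
       age = if (k >= 1) cols$age[k] else NA_real_)
}

#' Decide the next scheduled exam
#'
#' Pure function of (exam history, policy, current age). Routine exams run
#' at the policy interval until the stopping age; any colonoscopy that
#' detects adenomas moves the person to the surveillance track, whose
#' intervals come from the two most recent colonoscopy findings; a normal
#' first (screening or diagnostic) colonoscopy postpones routine screening
#' until 10 years after that exam (or the routine interval, if larger than
#' 10). Once on surveillance a person stays colonoscopy-based until the
#' stopping rules end surveillance.
#'
#' @param history a [exam_history()].
#' @param policy a [screening_policy()].
#' @param now current age.
#' @param table a [surveillance_table()].
#' @return list `(age, modality, kind)`, or `NULL` when no further exam is
#'   scheduled.
#' @export
next_event <- function(history, policy, now,
                       table = surveillance_table()) {
  if (nrow(history) > 0 && any(history$category %in% "crc")) return(NULL)
  lt <- last_two_colonoscopy_findings(history)
  on_surveillance <- any(history$category %in% findings_categories()[3:6])

  if (on_surveillance) {
    iv <- surveillance_interval(lt$second, lt$first, table)
    proposed <- lt$age + iv
    dec <- apply_stopping_rules(history, policy, proposed, kind = "surveillance")
    if (dec == "drop") return(NULL)
    return(list(age = proposed, modality = "colonoscopy",
                kind = "surveillance"))
  }

  # routine track; a normal colonoscopy defers resumption
  resume_floor <- if (!is.na(lt$age) && lt$first == "normal")
    lt$age + max(10, policy$interval) else -Inf
  last_routine <- history$age[history$kind == "screening"]
  base <- if (length(last_routine)) max(last_routine) + policy$interval
          else policy$start_age
  proposed <- max(base, now)
  # exams skipped while waiting out a normal colonoscopy resume at the
  # first routine age not before the floor
  if (proposed < resume_floor) {
    k <- ceiling((resume_floor - base) / policy$interval - 1e-9)
    proposed <- base + k * policy$interval
  }
  dec <- apply_stopping_rules(history, policy, proposed, kind = "screening")
  if (dec == "drop") return(NULL)
  list(age = proposed, modality = policy$modality, kind = "screening")
}

#' Apply screening and surveillance stopping rules
#'
#' Routine exams are dropped after the policy stopping age. Surveillance
#' continues past the surveillance stopping age (85) only while the most
#' recent exam detected adenomas: an exam proposed beyond that age after a
#' negative (normal) exam is dropped.
#'
#' @inheritParams next_event
#' @param proposed_age age of the proposed exam.
#' @param kind "screening" or "surveillance".
#' @return `"schedule"` or `"drop"`.
#' @export
apply_stopping_rules <- function(history, policy, proposed_age,
                                 kind = c("screening", "surveillance")) {
  kind <- match.arg(kind)
  if (kind == "screening") {
    if (proposed_age > policy$stop_age + 1e-9) return("drop")
    return("schedule")
  }
  if (proposed_age <= policy$surveillance_stop_age + 1e-9) return("schedule")
  lt <- last_two_colonoscopy_findings(history)
  if (lt$first %in% findings_categories()[3:6]) "schedule" else "drop"
}
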