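# Pure-R reference implementation of the scenario replay engine.
#
# Mirrors src/engine.cpp draw-for-draw (same substreams, same exam-block
# counters), so that equality of the two engines on a common population is
# a meaningful cross-check of the compiled code. Slow; intended for tests
# and small worked examples only.

run_scenario_r_engine <- function(pop, sched_age, sched_mod, colo_sens,
                                  fit_sens, fit_spec, fit_per_lesion,
                                  surv_table, resume_gap, surv_stop_age,
                                  pandemic_age, delay_years, cutoff_age,
                                  survival_pars, seed) {
  n <- length(pop$oc_death_age)
  K <- length(sched_age)
  delay_end <- pandemic_age + delay_years
  ptr <- c(0, cumsum(pop$n_lesions))
  clin_ml <- survival_pars$clin_meanlog
  scr_ml <- survival_pars$screen_meanlog
  sdl <- survival_pars$sdlog

  death_age <- numeric(n); dx_age <- rep(NA_real_, n)
  crc_death_age <- rep(NA_real_, n); dx_mode <- integer(n)
  crc_death <- integer(n); n_colos <- integer(n); n_fits <- integer(n)

  size_class <- function(dt, t6, t10) ifelse(dt < t6, 1L, ifelse(dt < t10, 2L, 3L))

  for (i in seq_len(n)) {
    l0 <- ptr[i] + 1L; l1 <- ptr[i + 1L]
    idx <- if (l1 >= l0) l0:l1 else integer()
    removed <- rep(FALSE, length(idx))
    ocd <- pop$oc_death_age[i]
    onset <- pop$onset_age[idx]; t6 <- pop$t6[idx]; t10 <- pop$t10[idx]
    tra <- pop$transform_age[idx]; clin <- pop$clinical_age[idx]
    soj <- pop$sojourn[idx]; svu <- pop$surv_u[idx]
    reach <- pop$within_reach[idx] == 1

    last_cat <- 0L  # no_prior
    in_surv <- FALSE; done <- FALSE
    surv_due <- Inf; resume_age <- -Inf
    ridx <- 1L; exam_ct <- 0L; ncol <- 0L; nfit <- 0L
    p_dx <- NA_real_; p_crcd <- NA_real_; p_mode <- 0L

    exam_u <- function(slots) {
      rng_uniforms(seed, i, 4, exam_ct * 64 + slots)
    }
    earliest <- function() {
      act <- which(!removed & is.finite(clin))
      if (!length(act)) return(list(age = Inf, who = NA))
      w <- act[which.min(clin[act])]
      list(age = clin[w], who = w)
    }
    colonoscopy <- function(a) {
      u <- exam_u(0:63)
      exam_ct <<- exam_ct + 1L; ncol <<- ncol + 1L
      n_small <- 0L; n_large <- 0L; cancer <- NA_integer_
      for (j in seq_along(idx)) {
        if (removed[j] || onset[j] > a || !reach[j]) next
        uj <- u[j + 1]  # slot 1 + (j - 1), 1-based
        if (a < tra[j]) {
          sc <- size_class(a - onset[j], t6[j], t10[j])
          if (uj < colo_sens[sc]) {
            removed[j] <<- TRUE
            if (sc == 3L) n_large <- n_large + 1L else n_small <- n_small + 1L
          }
        } else if (a < clin[j]) {
          if (uj < colo_sens[4] && is.na(cancer)) cancer <- j
        }
      }
      if (!is.na(cancer)) {
        p_dx <<- a; p_mode <<- 1L
        p_crcd <<- a + stats::qlnorm(svu[cancer], scr_ml, sdl)
        done <<- TRUE
        return(invisible())
      }
      ndet <- n_small + n_large
      cat_ <- if (ndet == 0L) 1L
              else if (ndet > 10L) 5L
              else if (n_large > 0L || ndet >= 5L) 4L
              else if (ndet >= 3L) 3L else 2L
      second <- last_cat; last_cat <<- cat_
      if (cat_ == 1L) {
        if (in_surv) {
          iv <- surv_table[second + 1L, 2L]
          prop <- a + iv
          if (prop > surv_stop_age + 1e-9) { in_surv <<- FALSE; done <<- TRUE }
          else surv_due <<- prop
        } else resume_age <<- a + resume_gap
      } else {
        iv <- surv_table[second + 1L, cat_ + 1L]
        in_surv <<- TRUE
        surv_due <<- a + iv
      }
      invisible()
    }

    while (!done) {
      if (in_surv) {
        a <- surv_due
        if (delay_years > 0 && a >= pandemic_age && a < delay_end)
          a <- delay_end
        mod <- 0L
      } else {
        while (ridx <= K && sched_age[ridx] < resume_age - 1e-9)
          ridx <- ridx + 1L
        if (ridx > K) a <- Inf else { a <- sched_age[ridx]; mod <- sched_mod[ridx] }
      }
      if (a >= cutoff_age) a <- Inf
      ec <- earliest()
      if (ec$age < a && ec$age < ocd) {
        p_dx <- ec$age; p_mode <- 2L
        p_crcd <- ec$age + stats::qlnorm(svu[ec$who], clin_ml, sdl)
        break
      }
      if (!is.finite(a) || a >= ocd) break
      if (mod == 1L) {  # FIT
        u <- exam_u(0:63)
        exam_ct <- exam_ct + 1L; nfit <- nfit + 1L
        prev <- which(!removed & onset <= a)
        pos <- FALSE
        if (fit_per_lesion == 1L) {
          pos <- u[1] < (1 - fit_spec)
          for (j in prev) {
            s <- if (a < tra[j])
              fit_sens[size_class(a - onset[j], t6[j], t10[j])]
            else if (a - tra[j] < 0.5 * soj[j]) fit_sens[4] else fit_sens[5]
            if (u[j + 1] < s) pos <- TRUE
          }
        } else {
          s <- 1 - fit_spec; best <- -1
          for (j in prev) {
            if (a < tra[j]) {
              sc <- size_class(a - onset[j], t6[j], t10[j])
              rnk <- sc - 1; sj <- fit_sens[sc]
            } else {
              late <- (a - tra[j]) >= 0.5 * soj[j]
              rnk <- if (late) 4 else 3
              sj <- if (late) fit_sens[5] else fit_sens[4]
            }
            if (rnk > best) { best <- rnk; s <- sj }
          }
          pos <- u[1] < s
        }
        ridx <- ridx + 1L
        if (pos) colonoscopy(a)
      } else {
        if (!in_surv) ridx <- ridx + 1L
        colonoscopy(a)
      }
    }

    if (p_mode == 0L) {
      ec <- earliest()
      if (ec$age < ocd) {
        p_dx <- ec$age; p_mode <- 2L
        p_crcd <- ec$age + stats::qlnorm(svu[ec$who], clin_ml, sdl)
      }
    }
    da <- ocd; crcd <- 0L
    if (p_mode != 0L && is.finite(p_crcd) && p_crcd < ocd) { da <- p_crcd; crcd <- 1L }
    death_age[i] <- da
    dx_age[i] <- if (p_mode != 0L) p_dx else NA_real_
    crc_death_age[i] <- if (p_mode != 0L) p_crcd else NA_real_
    dx_mode[i] <- p_mode; crc_death[i] <- crcd
    n_colos[i] <- ncol; n_fits[i] <- nfit
  }
  list(death_age = death_age, dx_age = dx_age,
       crc_death_age = crc_death_age, dx_mode = dx_mode,
       crc_death = crc_death, n_colonoscopies = n_colos, n_fits = n_fits)
}
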