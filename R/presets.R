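#' Natural-history model presets
#'
#' A preset bundles every parameter of the adenoma-carcinoma natural
#' history: the piecewise-constant baseline adenoma onset hazard, the
#' person-level frailty on that hazard, per-lesion exponential diameter
#' growth (1 mm at onset, size classes 1-5 mm / 6-9 mm / >=10 mm at the
#' 6 mm and 10 mm thresholds), size-class-dependent annual probabilities of
#' malignant transformation, the preclinical sojourn-time distribution,
#' lognormal survival after diagnosis (screen-detected survival
#' stochastically dominates clinically detected survival by construction),
#' and the FIT positivity profile used with the preset.
#'
#' Two bundled presets, `"preset-A"` and `"preset-B"`, play the role of the
#' two independently parameterized models whose cross-model output ranges
#' the package reports. They differ in onset hazard, frailty, growth,
#' sojourn (A: lognormal, mean about 3.5 y; B: exponential, mean 5 y) and
#' FIT positivity mode (A: per-person; B: per-lesion). Neither is a
#' calibrated registry model; both were tuned once so that lifetime
#' unscreened CRC incidence falls in a plausible 4-7% band.
#'
#' @param label preset name.
#' @param adenoma_onset list: `age_breaks` (K+1 increasing ages),
#'   `base_hazard` (K non-negative per-year hazards), `frailty_dist`
#'   ("gamma" or "lognormal"), `frailty_var` (>= 0), `max_lesions`.
#' @param growth list: `rate_meanlog`, `rate_sdlog` of the lognormal
#'   diameter growth rate (diameter = exp(rate * years) mm), `reach_prob`
#'   probability a lesion is within reach of the scope.
#' @param transformation list: `small`, `medium`, `large` annual
#'   transformation probabilities in [0, 1).
#' @param sojourn list: `dist` ("lognormal" or "exponential") plus
#'   `meanlog`/`sdlog` or `mean`.
#' @param crc_survival list: `clin_meanlog`, `screen_meanlog`, `sdlog` of
#'   lognormal survival after diagnosis (years); `screen_meanlog` must be
#'   >= `clin_meanlog`.
#' @param fit list: `mode` ("per_person" or "per_lesion"), `sens` with
#'   `small`/`medium`/`large`, `sens_preclinical` length-2 (early, late),
#'   `specificity`.
#' @return an object of class `crc_preset`.
#' @seealso [default_presets()], [read_preset()]
#' @export
crc_preset <- function(label, adenoma_onset, growth, transformation,
                       sojourn, crc_survival, fit) {
  p <- structure(list(label = label, adenoma_onset = adenoma_onset,
                      growth = growth, transformation = transformation,
                      sojourn = sojourn, crc_survival = crc_survival,
                      fit = fit),
                 class = "crc_preset")
  validate_preset(p)
}

validate_preset <- function(p) {
  ao <- p$adenoma_onset
  if (length(ao$base_hazard) != length(ao$age_breaks) - 1L)
    stop("base_hazard must have one entry per age interval")
  if (any(ao$base_hazard < 0)) stop("onset hazards must be non-negative")
  if (is.unsorted(ao$age_breaks, strictly = TRUE))
    stop("age_breaks must be strictly increasing")
  if (ao$frailty_var < 0) stop("frailty variance must be non-negative")
  if (!ao$frailty_dist %in% c("gamma", "lognormal"))
    stop("frailty_dist must be 'gamma' or 'lognormal'")
  tr <- unlist(p$transformation[c("small", "medium", "large")])
  if (any(tr < 0 | tr >= 1))
    stop("transformation probabilities must be in [0, 1)")
  if (!p$sojourn$dist %in% c("lognormal", "exponential"))
    stop("sojourn dist must be 'lognormal' or 'exponential'")
  if (p$growth$reach_prob < 0 || p$growth$reach_prob > 1)
    stop("reach_prob must be a probability")
  if (p$crc_survival$screen_meanlog < p$crc_survival$clin_meanlog)
    stop("screen-detected survival must dominate clinically detected survival")
  fs <- unlist(p$fit$sens[c("small", "medium", "large")])
  if (any(fs < 0 | fs > 1) || any(p$fit$sens_preclinical < 0) ||
      any(p$fit$sens_preclinical > 1) ||
      p$fit$specificity < 0 || p$fit$specificity > 1)
    stop("FIT sensitivities and specificity must be probabilities")
  if (!p$fit$mode %in% c("per_person", "per_lesion"))
    stop("fit mode must be 'per_person' or 'per_lesion'")
  p
}

#' @export
print.crc_preset <- function(x, ...) {
  cat("<crc_preset>", x$label, "\n")
  cat("  onset: ", length(x$adenoma_onset$base_hazard),
      " hazard segments, frailty ", x$adenoma_onset$frailty_dist,
      " (var ", x$adenoma_onset$frailty_var, ")\n", sep = "")
  cat("  transformation p/yr:",
      paste(sprintf("%.4g", unlist(x$transformation[c("small", "medium", "large")])),
            collapse = " / "), "\n")
  cat("  sojourn:", x$sojourn$dist, "\n")
  cat("  FIT positivity:", x$fit$mode, "\n")
  invisible(x)
}

# flatten a preset for the compiled engine
preset_engine_pars <- function(p) {
  sj <- p$sojourn
  list(age_breaks = as.double(p$adenoma_onset$age_breaks),
       base_hazard = as.double(p$adenoma_onset$base_hazard),
       frailty_dist = if (p$adenoma_onset$frailty_dist == "gamma") 0L else 1L,
       frailty_var = as.double(p$adenoma_onset$frailty_var),
       max_lesions = as.integer(p$adenoma_onset$max_lesions),
       growth_meanlog = as.double(p$growth$rate_meanlog),
       growth_sdlog = as.double(p$growth$rate_sdlog),
       reach_prob = as.double(p$growth$reach_prob),
       transform_small = as.double(p$transformation$small),
       transform_medium = as.double(p$transformation$medium),
       transform_large = as.double(p$transformation$large),
       sojourn_dist = if (sj$dist == "lognormal") 0L else 1L,
       sojourn_par1 = as.double(if (sj$dist == "lognormal") sj$meanlog else sj$mean),
       sojourn_par2 = as.double(if (sj$dist == "lognormal") sj$sdlog else 0),
       surv_clin_meanlog = as.double(p$crc_survival$clin_meanlog),
       surv_screen_meanlog = as.double(p$crc_survival$screen_meanlog),
       surv_sdlog = as.double(p$crc_survival$sdlog))
}

#' The two bundled model presets
#'
#' Reads the preset definitions shipped with the package
#' (`inst/extdata/preset-A.yaml`, `preset-B.yaml`). Preset A pairs its
#' natural history with per-person FIT positivity; preset B uses
#' per-lesion positivity. Both share the colonoscopy profiles.
#'
#' @return named list of two `crc_preset` objects.
#' @export
default_presets <- function() {
  a <- read_preset(system.file("extdata", "preset-A.yaml",
                               package = "crcdisrupt", mustWork = TRUE))
  b <- read_preset(system.file("extdata", "preset-B.yaml",
                               package = "crcdisrupt", mustWork = TRUE))
  stats::setNames(list(a, b), c(a$label, b$label))
}

#' Read or write a preset YAML file
#'
#' @param path YAML file path.
#' @return `read_preset` returns a `crc_preset`.
#' @export
read_preset <- function(path) {
  y <- yaml::read_yaml(path)
  crc_preset(label = y$label, adenoma_onset = y$adenoma_onset,
             growth = y$growth, transformation = y$transformation,
             sojourn = y$sojourn, crc_survival = y$crc_survival,
             fit = y$fit)
}

#' @rdname read_preset
#' @param preset a `crc_preset`.
#' @export
write_preset <- function(preset, path) {
  yaml::write_yaml(unclass(preset), path)
  invisible(path)
}

#' Screening test profiles (sensitivity and specificity)
#'
#' Per-lesion sensitivities by adenoma size class plus preclinical-cancer
#' sensitivity and specificity for one screening modality. The bundled
#' profiles reproduce the study's assumptions: colonoscopy high
#' (0.75/0.85/0.95 by size, 0.95 preclinical) and low (0.55/0.70/0.90,
#' 0.95); FIT per-person (0.05/0.15/0.22, 0.74 preclinical) and FIT
#' per-lesion (0.00/0.114/0.159, 0.62565 early / 0.886 late preclinical),
#' both with specificity 0.97. Colonoscopy specificity (0.86) is carried
#' for completeness but never used in simulation: it matters only for
#' burden/cost outcomes, which are out of scope here.
#'
#' @param modality "colonoscopy" or "fit".
#' @param sens_small,sens_medium,sens_large per-lesion sensitivity by size.
#' @param sens_preclinical length-1 or length-2 (early, late) sensitivity
#'   for preclinical cancer.
#' @param specificity test specificity.
#' @param positivity_mode "per_lesion" or "per_person" (FIT only).
#' @param scenario_label "high" or "low" for colonoscopy profiles.
#' @return an object of class `crc_test_profile`.
#' @export
test_profile <- function(modality, sens_small, sens_medium, sens_large,
                         sens_preclinical, specificity,
                         positivity_mode = "per_lesion",
                         scenario_label = NA_character_) {
  stopifnot(modality %in% c("colonoscopy", "fit"))
  pr <- c(sens_small, sens_medium, sens_large, sens_preclinical, specificity)
  if (any(pr < 0 | pr > 1)) stop("probabilities must be in [0, 1]")
  if (sens_small > sens_medium || sens_medium > sens_large)
    stop("sensitivity must be non-decreasing in size class")
  if (length(sens_preclinical) == 1L)
    sens_preclinical <- rep(sens_preclinical, 2L)
  structure(list(modality = modality, sens_small = sens_small,
                 sens_medium = sens_medium, sens_large = sens_large,
                 sens_preclinical = sens_preclinical,
                 specificity = specificity,
                 positivity_mode = positivity_mode,
                 scenario_label = scenario_label),
            class = "crc_test_profile")
}

#' @export
print.crc_test_profile <- function(x, ...) {
  cat("<crc_test_profile> ", x$modality,
      if (!is.na(x$scenario_label)) paste0(" (", x$scenario_label, ")"),
      "\n  sens by size: ", x$sens_small, " / ", x$sens_medium, " / ",
      x$sens_large, "; preclinical ",
      paste(unique(x$sens_preclinical), collapse = "/"),
      "; specificity ", x$specificity, "\n", sep = "")
  if (x$modality == "fit") cat("  positivity:", x$positivity_mode, "\n")
  invisible(x)
}

#' Bundled test profiles
#'
#' @return named list: `colonoscopy_high`, `colonoscopy_low`,
#'   `fit_per_person`, `fit_per_lesion`.
#' @export
default_test_profiles <- function() {
  path <- system.file("extdata", "test_profiles.csv",
                      package = "crcdisrupt", mustWork = TRUE)
  df <- utils::read.csv(path)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    test_profile(r$modality, r$sens_small, r$sens_medium, r$sens_large,
                 c(r$sens_preclinical_early, r$sens_preclinical_late),
                 r$specificity, r$positivity_mode, r$scenario_label)
  })
  stats::setNames(out, df$name)
}

#' Profiles used by a simulation run
#'
#' `colonoscopy_profile` returns the bundled colonoscopy profile for a
#' sensitivity scenario; `fit_profile_for` builds the FIT profile a preset
#' pairs with (its positivity mode and sensitivities).
#'
#' @param sensitivity "high" or "low".
#' @return a `crc_test_profile`.
#' @export
colonoscopy_profile <- function(sensitivity = c("high", "low")) {
  sensitivity <- match.arg(sensitivity)
  default_test_profiles()[[paste0("colonoscopy_", sensitivity)]]
}

#' @rdname colonoscopy_profile
#' @param preset a [crc_preset()].
#' @export
fit_profile_for <- function(preset) {
  f <- preset$fit
  test_profile("fit", f$sens$small, f$sens$medium, f$sens$large,
               as.numeric(f$sens_preclinical), f$specificity, f$mode,
               preset$label)
}
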