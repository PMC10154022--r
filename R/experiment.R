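#' Run a set of disruption scenarios across model presets
#'
#' The top-level driver: for every requested scenario x preset x
#' colonoscopy-sensitivity combination it simulates the three arms
#' (no screening, no disruption, disrupted) on a shared population and
#' collects the outcome accounting. Within a preset, each cohort's
#' population is generated once and reused across that cohort's scenarios.
#'
#' @param scenarios character vector of scenario labels (default: the full
#'   study set, see [scenario_labels()]).
#' @param n persons simulated per cohort.
#' @param seed root seed; every random draw in the experiment derives from
#'   it.
#' @param presets list of [crc_preset()] objects (default both bundled
#'   presets).
#' @param sensitivities colonoscopy sensitivity scenarios to run.
#' @param life_table a [make_life_table()] table.
#' @return object of class `crc_experiment`: `results` (a data.frame with
#'   one row per scenario x preset x sensitivity), `outcome_sets`, the
#'   run `manifest` (seed, n, labels, wall time, package version).
#' @examples
#' \donttest{
#' ex <- run_experiment(c("C60 | C18m", "C60 | U"), n = 2000, seed = 7)
#' summary(ex)
#' }
#' @export
run_experiment <- function(scenarios = scenario_labels(), n = 10000,
                           seed = 1, presets = default_presets(),
                           sensitivities = "high",
                           life_table = make_life_table()) {
  t0 <- Sys.time()
  parsed <- lapply(scenarios, parse_scenario_code)  # errors before simulating
  osets <- list()
  rows <- list()
  for (preset in presets) {
    pops <- list()
    for (sens in sensitivities) {
      for (sc in parsed) {
        code <- sc$cohort$code
        if (is.null(pops[[code]]))
          pops[[code]] <- generate_population(preset, life_table,
                                              sc$cohort$birth_year, n, seed)
        run <- run_scenario(sc, preset = preset, n = n, seed = seed,
                            sensitivity = sens, life_table = life_table,
                            population = pops[[code]])
        o <- run$outcomes
        key <- paste(o$scenario_label, o$preset_label, sens, sep = " / ")
        osets[[key]] <- o
        rows[[key]] <- data.frame(
          scenario = o$scenario_label, model = o$preset_label,
          sensitivity = sens, n = o$n,
          LY_no_screening = o$LYNS, LY_no_disruption = o$LYND,
          LYG_no_disruption = o$LYG_no_disruption, LY = o$LY,
          LYG_disrupted = o$LY - o$LYNS, LYL = o$LYL,
          pct_LY_lost = o$pct_LY_lost,
          life_days_lost_per_person = life_days_per_person(o$LYL),
          crc_cases_per_1000 = o$crc_cases_per_1000,
          crc_deaths_per_1000 = o$crc_deaths_per_1000,
          mc_se_LYL = unname(o$mc_se["LYL"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  manifest <- list(seed = seed, n = n, scenarios = scenarios,
                   presets = names(presets),
                   sensitivities = sensitivities,
                   package_version = as.character(utils::packageVersion("crcdisrupt")),
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  structure(list(results = results, outcome_sets = osets,
                 manifest = manifest),
            class = "crc_experiment")
}

#' Read an experiment configuration from YAML
#'
#' Keys: `scenarios`, `n`, `seed`, `sensitivities`, optional
#' `life_table_csv` and `preset_files`. A run is reproducible from the
#' configuration alone.
#'
#' @param path YAML file.
#' @return list of arguments for [run_experiment()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(scenarios = unlist(y$scenarios %||% scenario_labels()),
               n = y$n %||% 10000, seed = y$seed %||% 1,
               sensitivities = unlist(y$sensitivities %||% "high"))
  if (!is.null(y$life_table_csv))
    args$life_table <- read_life_table(y$life_table_csv)
  if (!is.null(y$preset_files)) {
    pl <- lapply(unlist(y$preset_files), read_preset)
    args$presets <- stats::setNames(pl, vapply(pl, `[[`, "", "label"))
  }
  args
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.crc_experiment <- function(x, ...) {
  m <- x$manifest
  cat("<crc_experiment>", nrow(x$results), "scenario x model rows,",
      "n =", m$n, "per cohort, seed", m$seed, "\n")
  cat("  presets:", paste(m$presets, collapse = ", "),
      "; sensitivity:", paste(m$sensitivities, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.crc_experiment <- function(object, ...) {
  df <- render_table(object)
  cat("Projected life-years per 1000 individuals (rounded as reported):\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' Render the experiment as a report table
#'
#' One row per scenario x model with the life-year columns rounded to
#' integers and the percent loss to the nearest integer, in the order
#' no-screening LY, no-disruption LY and LYG, disrupted LY and LYG, LYL,
#' percent LYG lost.
#'
#' @param experiment a `crc_experiment`.
#' @return data.frame.
#' @export
render_table <- function(experiment) {
  r <- experiment$results
  data.frame(scenario = r$scenario, model = r$model,
             sensitivity = r$sensitivity,
             LY_ns = round(r$LY_no_screening),
             LY_nd = round(r$LY_no_disruption),
             LYG = round(r$LYG_no_disruption),
             LY = round(r$LY),
             LYG_disrupted = round(r$LYG_disrupted),
             LYL = round(r$LYL),
             pct_loss = round(r$pct_LY_lost),
             stringsAsFactors = FALSE)
}

#' Dot-plot data: benefit lost by scenario
#'
#' Scenario/model rows of life-years lost per 1000 and life-days lost per
#' person, sorted from highest to lowest reduction in benefit, omitting
#' scenarios where every model estimates under `min_life_days` (2) lost
#' life-days per person.
#'
#' @param experiment a `crc_experiment`.
#' @param min_life_days omission threshold in life-days per person.
#' @return data.frame sorted by descending LYL.
#' @export
render_dotplot_data <- function(experiment, min_life_days = 2) {
  r <- experiment$results
  keep_sc <- vapply(split(r$life_days_lost_per_person, r$scenario), max,
                    numeric(1))
  keep <- r$scenario %in% names(keep_sc)[keep_sc >= min_life_days]
  if (!any(keep)) {
    message("all scenarios fall under ", min_life_days,
            " life-days lost per person; dot-plot data is empty")
    return(r[0, c("scenario", "model", "LYL", "life_days_lost_per_person")])
  }
  out <- r[keep, c("scenario", "model", "LYL",
                   "life_days_lost_per_person")]
  out[order(-out$LYL), , drop = FALSE]
}

#' Min-max ranges across models for each scenario
#'
#' @param experiment a `crc_experiment`.
#' @return data.frame with one row per scenario x sensitivity and
#'   min/max columns for LYL, LYG and percent lost across presets.
#' @export
experiment_ranges <- function(experiment) {
  r <- experiment$results
  sp <- split(r, list(r$scenario, r$sensitivity), drop = TRUE)
  out <- lapply(sp, function(d) data.frame(
    scenario = d$scenario[1], sensitivity = d$sensitivity[1],
    LYL_min = min(d$LYL), LYL_max = max(d$LYL),
    LYG_min = min(d$LYG_no_disruption), LYG_max = max(d$LYG_no_disruption),
    pct_min = min(d$pct_LY_lost), pct_max = max(d$pct_LY_lost),
    stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot life-years lost by scenario
#'
#' Base-graphics dot plot of the filtered, sorted [render_dotplot_data()],
#' one dot per model.
#'
#' @param x a `crc_experiment`.
#' @param min_life_days omission threshold.
#' @param ... passed to [graphics::plot()].
#' @export
plot.crc_experiment <- function(x, min_life_days = 2, ...) {
  d <- render_dotplot_data(x, min_life_days)
  if (!nrow(d)) return(invisible(NULL))
  scen <- factor(d$scenario, levels = rev(unique(d$scenario)))
  graphics::plot(d$LYL, as.integer(scen), yaxt = "n",
                 xlab = "Life-years lost per 1000 persons", ylab = "",
                 pch = 19,
                 col = as.integer(factor(d$model)), ...)
  graphics::axis(2, at = seq_len(nlevels(scen)), labels = levels(scen),
                 las = 1, cex.axis = 0.7)
  graphics::legend("bottomright", legend = levels(factor(d$model)),
                   col = seq_len(nlevels(factor(d$model))), pch = 19,
                   bty = "n")
  invisible(d)
}

#' Export the bundled fixtures
#'
#' Writes the cohort life table, the two preset YAML files, and the test
#' characteristics and surveillance interval tables to a directory.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  lt <- file.path(dir, "life_table.csv")
  write_life_table(make_life_table(), lt)
  paths <- c(paths, lt)
  for (p in default_presets()) {
    f <- file.path(dir, paste0(p$label, ".yaml"))
    write_preset(p, f)
    paths <- c(paths, f)
  }
  for (f in c("test_profiles.csv", "surveillance_intervals.csv")) {
    src <- system.file("extdata", f, package = "crcdisrupt", mustWork = TRUE)
    file.copy(src, file.path(dir, f), overwrite = TRUE)
    paths <- c(paths, file.path(dir, f))
  }
  invisible(paths)
}
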