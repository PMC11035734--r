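#' Link dispensations to their statin prescriptions
#'
#' Keeps dispensations whose `prescription_id` matches a retained
#' prescription and that satisfy the record-linkage invariants: the
#' dispense date must not precede the issue date and the dispensed quantity
#' must not exceed the prescribed quantity (partial fills are allowed).
#' Violations and orphans are dropped and counted in the attached log.
#'
#' @param dispensations,prescriptions Registry tibbles.
#' @return The filtered dispensations tibble (diagnostics via
#'   [reader_log()]).
#' @export
link_dispensations <- function(dispensations, prescriptions) {
  joined <- dispensations |>
    left_join(prescriptions |>
                select("prescription_id", "issue_date",
                       rx_tablets = "tablets"),
              by = "prescription_id")
  orphan <- is.na(joined$issue_date)
  early <- !orphan & joined$dispense_date < joined$issue_date
  over <- !orphan & !early & joined$tablets > joined$rx_tablets
  keep <- !(orphan | early | over)
  out <- dispensations[keep, , drop = FALSE]
  log <- tibble(
    table = "dispensations",
    issue = c("orphan_prescription", "dispensed_before_issue",
              "dispensed_over_prescribed"),
    n = c(sum(orphan), sum(early), sum(over))
  )
  log <- log[log$n > 0, ]
  if (nrow(log)) {
    inform(paste0("dispensations: dropped ", sum(log$n), " row(s) (",
                  paste(sprintf("%s: %d", log$issue, log$n), collapse = "; "),
                  ")"))
  }
  rxflow_log(out, log)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. All study constants
#' (the 0.80/0.90 adherence thresholds, the 30-day grace period, the
#' 30-tablet standard pack, the 100,000-patient persistence sample) live
#' here as defaults, never at call sites.
#'
#' @param prescriptions,dispensations,patients,covid Input CSV paths
#'   (`patients` and `covid` optional).
#' @param out_dir Output directory for the report bundle.
#' @param window A [study_window()].
#' @param population Population table (see [default_population()]).
#' @param lockdowns A [lockdown_calendar()].
#' @param adherence_thresholds Possession thresholds.
#' @param grace_days Persistence grace period in days.
#' @param pack_size Tablets per standard pack.
#' @param persistence_start,persistence_end Persistence analysis window.
#' @param persistence_n Size of the random persistence subcohort.
#' @param seed Seed for the persistence sampling.
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @param carryover Honour refill stockpiling in supply timelines.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(prescriptions, dispensations, patients = NULL,
                            covid = NULL, out_dir = tempfile("rxflow_out"),
                            window = study_window(),
                            population = default_population(),
                            lockdowns = lockdown_calendar(),
                            adherence_thresholds = c(0.80, 0.90),
                            grace_days = 30,
                            pack_size = 30,
                            persistence_start = as.Date("2022-01-01"),
                            persistence_end = as.Date("2022-12-31"),
                            persistence_n = 100000,
                            seed = 1L,
                            correlation_method = "spearman",
                            carryover = TRUE) {
  cfg <- as.list(environment())
  cfg$window <- as_study_window(window)
  if (any(adherence_thresholds <= 0 | adherence_thresholds > 1)) {
    abort("`adherence_thresholds` must lie in (0, 1].")
  }
  if (grace_days < 0) abort("`grace_days` must be >= 0.")
  if (pack_size <= 0) abort("`pack_size` must be positive.")
  cfg$persistence_start <- as.Date(persistence_start)
  cfg$persistence_end <- as.Date(persistence_end)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments;
#' `window` is a `start`/`end` pair, `lockdowns` a list of
#' `iso_year`/`week_from`/`week_to` triples, `population` a list of
#' `year`/`population` pairs. Unknown keys raise an error.
#'
#' @param path YAML file path.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read YAML configurations.")
  }
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(y$window)) y$window <- study_window(y$window$start, y$window$end)
  if (!is.null(y$lockdowns)) {
    y$lockdowns <- lockdown_calendar(bind_rows(y$lockdowns))
  }
  if (!is.null(y$population)) y$population <- bind_rows(y$population)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[", name, "] ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates ingest -> statin filter -> weekly aggregation -> adherence
#' -> persistence -> COVID/lockdown context, and writes the report bundle
#' to `config$out_dir`: `weekly_series.csv`, `adherence.csv`,
#' `persistence.csv`, `km_curve.csv`, `covid_report.json`, `summary.json`
#' and `run_log.json` (seed, configuration hash, row counts). Reruns with
#' the same configuration and seed produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with every intermediate result (`registry`,
#'   `weekly`, `adherence`, `adherence_summary`, `persistence`, `km`,
#'   `persistence_summary`, `covid_report`, `summary`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  reg <- stage("ingest", read_registry(config$prescriptions,
                                       config$dispensations,
                                       config$patients, quiet = quiet))
  say("ingest: %d prescriptions, %d dispensations, %s patients",
      nrow(reg$prescriptions), nrow(reg$dispensations),
      if (is.null(reg$patients)) "no" else nrow(reg$patients))

  rx <- stage("statin_filter", filter_statin_atc(reg$prescriptions))
  disp <- stage("statin_filter", link_dispensations(reg$dispensations, rx))
  included <- stage("inclusion", include_patients(disp, config$window))
  say("inclusion: %d statin prescriptions, %d dispensations, %d patients",
      nrow(rx), nrow(disp), length(included))

  weekly <- stage("weekly", {
    aggregate_weekly(rx, disp, config$window) |>
      percent_dispensed() |>
      per_capita_rate(config$population) |>
      lockdown_flags(config$lockdowns)
  })
  covid <- NULL
  if (!is.null(config$covid)) {
    covid <- stage("covid_ingest",
                   read_ecdc_weekly(config$covid, window = config$window))
    weekly <- weekly |>
      left_join(select(covid, "iso_year", "iso_week", "covid_cases",
                       "covid_deaths"),
                by = c("iso_year", "iso_week"))
  }

  trend_rx <- stage("trends", fit_linear_trend(weekly, .data$prescribed_tablets))
  trend_dx <- stage("trends", fit_linear_trend(weekly, .data$dispensed_tablets))
  trend_pct <- stage("trends", fit_linear_trend(weekly, .data$pct_dispensed))
  quarters <- stage("trends", aggregate_quarters(weekly, .data$pct_dispensed))
  years <- stage("trends", compare_years(weekly, .data$pct_dispensed))

  adherence <- stage("adherence",
                     adherence_records(disp, reg$patients, config$window,
                                       thresholds = config$adherence_thresholds,
                                       carryover = config$carryover))
  adherence_summary <- stage("adherence",
                             cohort_adherence(adherence,
                                              config$adherence_thresholds))

  timelines <- stage("persistence",
                     build_supply_timelines(disp, carryover = config$carryover))
  eligible <- stage("persistence",
                    persistence_cohort(disp, config$persistence_start,
                                       carryover = config$carryover))
  sampled <- stage("persistence",
                   sample_persistence_cohort(eligible, config$persistence_n,
                                             config$seed))
  outcomes <- stage("persistence",
                    detect_discontinuation(timelines,
                                           config$persistence_start,
                                           config$persistence_end,
                                           grace_days = config$grace_days,
                                           patients = reg$patients,
                                           ids = sampled))
  km <- stage("persistence", kaplan_meier(outcomes))
  persistence_summary <- stage("persistence", summarize_persistence(outcomes))
  say("persistence: %d eligible, %d sampled, S(12m) = %.3f",
      length(eligible), length(sampled), persistence_summary$persistence_at)

  covid_report <- NULL
  if (!is.null(covid)) {
    covid_report <- stage("covid_context", list(
      correlations = bind_rows(
        cases_vs_dispensed = correlate_series(weekly$covid_cases,
                                              weekly$dispensed_tablets,
                                              config$correlation_method),
        cases_vs_prescribed = correlate_series(weekly$covid_cases,
                                               weekly$prescribed_tablets,
                                               config$correlation_method),
        deaths_vs_dispensed = correlate_series(weekly$covid_deaths,
                                               weekly$dispensed_tablets,
                                               config$correlation_method),
        deaths_vs_prescribed = correlate_series(weekly$covid_deaths,
                                                weekly$prescribed_tablets,
                                                config$correlation_method),
        cases_vs_pct_dispensed = correlate_series(weekly$covid_cases,
                                                  weekly$pct_dispensed,
                                                  config$correlation_method),
        deaths_vs_pct_dispensed = correlate_series(weekly$covid_deaths,
                                                   weekly$pct_dispensed,
                                                   config$correlation_method),
        .id = "pair"
      ),
      lockdown_prescribed = compare_lockdown(weekly, .data$prescribed_tablets),
      lockdown_dispensed = compare_lockdown(weekly, .data$dispensed_tablets),
      lockdown_pct = compare_lockdown(weekly, .data$pct_dispensed),
      lockdown_pct_location = weekly |>
        summarise(median_lockdown = median(.data$pct_dispensed[.data$lockdown],
                                           na.rm = TRUE),
                  median_other = median(.data$pct_dispensed[!.data$lockdown],
                                        na.rm = TRUE),
                  sd_lockdown = sd(.data$pct_dispensed[.data$lockdown],
                                   na.rm = TRUE),
                  sd_other = sd(.data$pct_dispensed[!.data$lockdown],
                                na.rm = TRUE)),
      lockdown_deficit_adjusted = list(
        prescribed = estimate_lockdown_deficit(weekly, .data$prescribed_tablets),
        dispensed = estimate_lockdown_deficit(weekly, .data$dispensed_tablets)
      ),
      matched_weeks = matched_week_comparison(weekly, .data$pct_dispensed,
                                              config$lockdowns),
      note = "p-values are reported without multiple-testing correction"
    ))
  }

  total_rx <- sum(weekly$prescribed_tablets)
  total_dx <- sum(weekly$dispensed_tablets)
  summary <- list(
    window = list(start = format(config$window$start),
                  end = format(config$window$end),
                  n_weeks = nrow(weekly)),
    cohort = list(
      n_patients = length(included),
      n_deaths = if (!is.null(reg$patients)) {
        sum(reg$patients$patient_id %in% included &
              !is.na(reg$patients$death_date))
      } else NA,
      sex = if (!is.null(reg$patients)) {
        as.list(table(reg$patients$sex[reg$patients$patient_id %in% included]))
      } else NULL
    ),
    totals = list(
      prescribed_tablets = total_rx,
      dispensed_tablets = total_dx,
      prescribed_packs = tablets_to_packs(total_rx, config$pack_size),
      dispensed_packs = tablets_to_packs(total_dx, config$pack_size),
      overall_fill_pct = overall_fill_percentage(total_dx, total_rx)
    ),
    trends = list(
      prescribed = list(slope = trend_rx$slope, p_value = trend_rx$p_value,
                        fitted_first = trend_rx$fitted_first,
                        fitted_last = trend_rx$fitted_last,
                        pct_change = percent_change_endpoints(
                          trend_rx$fitted_first, trend_rx$fitted_last)),
      dispensed = list(slope = trend_dx$slope, p_value = trend_dx$p_value,
                       fitted_first = trend_dx$fitted_first,
                       fitted_last = trend_dx$fitted_last,
                       pct_change = percent_change_endpoints(
                         trend_dx$fitted_first, trend_dx$fitted_last)),
      pct_dispensed = list(slope = trend_pct$slope,
                           p_value = trend_pct$p_value,
                           fitted_first = trend_pct$fitted_first,
                           fitted_last = trend_pct$fitted_last)
    ),
    quarters = quarters,
    year_comparison = list(H = years$statistic, df = years$df,
                           p_value = years$p_value, normal = years$normal,
                           groups = years$groups),
    adherence = adherence_summary,
    adherence_mean_mpr = list(mean = mean(adherence$mpr),
                              sd = sd(adherence$mpr)),
    persistence = as.list(persistence_summary)
  )

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  readr::write_csv(weekly, outp("weekly_series.csv"))
  readr::write_csv(adherence, outp("adherence.csv"))
  readr::write_csv(outcomes, outp("persistence.csv"))
  readr::write_csv(tidy(km), outp("km_curve.csv"))
  jsonlite::write_json(summary, outp("summary.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  if (!is.null(covid_report)) {
    jsonlite::write_json(covid_report, outp("covid_report.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  run_log <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    rows = list(prescriptions = nrow(reg$prescriptions),
                dispensations = nrow(reg$dispensations),
                statin_prescriptions = nrow(rx),
                statin_dispensations = nrow(disp),
                included_patients = length(included),
                persistence_eligible = length(eligible),
                persistence_sampled = length(sampled))
  )
  jsonlite::write_json(run_log, outp("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("report written to %s", config$out_dir)

  invisible(list(
    registry = list(prescriptions = rx, dispensations = disp,
                    patients = reg$patients),
    included = included, weekly = weekly, covid = covid,
    trends = list(prescribed = trend_rx, dispensed = trend_dx,
                  pct_dispensed = trend_pct),
    quarters = quarters, years = years,
    adherence = adherence, adherence_summary = adherence_summary,
    timelines = timelines, persistence = outcomes, km = km,
    persistence_summary = persistence_summary,
    covid_report = covid_report, summary = summary
  ))
}

#' Simulate a registry and write it as a CSV bundle
#'
#' Convenience wrapper: [simulate_cohort()] + [simulate_covid_series()] +
#' [write_registry()] + [write_covid_weekly()].
#'
#' @param dir Output directory.
#' @param params A [cohort_params()].
#' @param covid A [covid_params()].
#' @param window A [study_window()].
#' @param seed Integer seed (drives both generators).
#' @param lockdowns A [lockdown_calendar()].
#' @return Invisibly, a named vector of file paths.
#' @export
simulate_registry <- function(dir, params = cohort_params(),
                              covid = covid_params(),
                              window = study_window(), seed = 1L,
                              lockdowns = lockdown_calendar()) {
  cohort <- simulate_cohort(params, window, seed = seed, lockdowns = lockdowns)
  paths <- write_registry(cohort, dir)
  cv <- simulate_covid_series(covid, window, seed = seed + 1L)
  covid_path <- file.path(dir, "covid_weekly.csv")
  write_covid_weekly(cv, covid_path)
  invisible(c(paths, covid_weekly = covid_path))
}
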