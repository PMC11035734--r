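DAYS_PER_MONTH <- 365.25 / 12 # 30.4375

#' Patients on therapy at a baseline date
#'
#' Persistence is assessed for established users: patients whose stockpiled
#' supply covers the baseline day itself (a coverage interval containing
#' `at`), based on dispensations up to that day. This excludes former users
#' whose therapy already lapsed before baseline, so the persistence clock
#' starts for everyone in the "on therapy" state.
#'
#' @param dispensations Statin dispensation events.
#' @param at Baseline date (default 2022-01-01).
#' @param carryover Passed to [build_supply_timelines()].
#' @return Character vector of eligible patient ids.
#' @export
persistence_cohort <- function(dispensations, at = as.Date("2022-01-01"),
                               carryover = TRUE) {
  at <- as.Date(at)
  prior <- filter(dispensations, .data$dispense_date < at)
  if (nrow(prior) == 0) return(character())
  build_supply_timelines(prior, carryover = carryover) |>
    filter(.data$start <= at, .data$end > at) |>
    distinct(.data$patient_id) |>
    pull(.data$patient_id)
}

#' Draw a random persistence subcohort
#'
#' Uniform sampling without replacement, reproducible from the seed. If
#' fewer than `n` patients are eligible, all are taken with a warning.
#'
#' @param eligible Character vector of eligible patient ids.
#' @param n Sample size (default 100000).
#' @param seed Integer seed.
#' @return Character vector of sampled patient ids.
#' @export
sample_persistence_cohort <- function(eligible, n = 100000, seed = 1L) {
  if (n >= length(eligible)) {
    if (n > length(eligible)) {
      warn(sprintf("requested %d patients but only %d eligible; taking all",
                   n, length(eligible)))
    }
    return(eligible)
  }
  withr::with_seed(seed, sample(eligible, n))
}

#' Detect therapy discontinuation under a grace period
#'
#' Scans each patient's supply coverage forward from the analysis window
#' start (carry-in supply from earlier dispensations included).
#' Non-persistence occurs at the first supply-exhaustion date not followed
#' by renewed coverage within `grace_days`; the discontinuation is
#' timestamped at the exhaustion date itself, not at grace expiry. Patients
#' reaching death or the window end without such a gap are censored.
#'
#' `boundary` controls the right-edge convention for a patient whose supply
#' runs out close to the end of observation and who never refills within
#' the data: `"event"` (default) counts it as a discontinuation at the
#' exhaustion date -- the patient demonstrably stopped collecting within
#' the horizon, and the persistence curve stays interpretable through the
#' final month; `"censor"` insists on a fully elapsed grace period and
#' censors instead, which leaves the last `grace_days` of the window
#' structurally event-free.
#'
#' @param timelines Supply timelines covering the analysis period,
#'   *including* dispensations before `window_start` (carry-in).
#' @param window_start,window_end Analysis window (inclusive dates; default
#'   calendar year 2022).
#' @param grace_days Allowed gap after exhaustion before declaring
#'   discontinuation (default 30).
#' @param patients Optional patient table supplying `death_date` for
#'   censoring.
#' @param ids Optional patient ids to restrict to (e.g. a sampled cohort);
#'   ids absent from `timelines` get an immediate event at duration 0.
#' @param boundary Right-edge convention, `"event"` or `"censor"` (see
#'   Details).
#' @return A tibble of persistence outcomes: `patient_id`,
#'   `duration_months` (months of 30.4375 days), `duration_days`,
#'   `discontinued` (`TRUE` = event, `FALSE` = censored).
#' @export
detect_discontinuation <- function(timelines,
                                   window_start = as.Date("2022-01-01"),
                                   window_end = as.Date("2022-12-31"),
                                   grace_days = 30,
                                   patients = NULL,
                                   ids = NULL,
                                   boundary = c("event", "censor")) {
  boundary <- match.arg(boundary)
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (!is.null(ids)) timelines <- filter(timelines, .data$patient_id %in% ids)

  ws <- as.numeric(window_start)
  # censoring horizon: end of the last observed day (window is inclusive)
  horizon <- as.numeric(window_end) + 1

  cens <- timelines |> distinct(.data$patient_id)
  if (!is.null(ids)) cens <- tibble(patient_id = unique(ids))
  if (!is.null(patients) && "death_date" %in% names(patients)) {
    cens <- cens |>
      left_join(select(patients, "patient_id", "death_date"),
                by = "patient_id") |>
      mutate(censor_at = pmin(as.numeric(.data$death_date) + 1, horizon,
                              na.rm = TRUE)) |>
      select("patient_id", "censor_at")
  } else {
    cens <- mutate(cens, censor_at = horizon)
  }
  cens <- mutate(cens, censor_at = pmax(.data$censor_at, ws))

  events <- timelines |>
    mutate(s = as.numeric(.data$start), e = as.numeric(.data$end)) |>
    group_by(.data$patient_id) |>
    arrange(.data$s, .by_group = TRUE) |>
    mutate(next_s = lead(.data$s, default = Inf)) |>
    ungroup() |>
    inner_join(cens, by = "patient_id") |>
    # exhaustions at/after window start, before censoring, with no renewed
    # coverage inside the grace period
    filter(.data$e >= ws, .data$e < .data$censor_at,
           .data$next_s > .data$e + grace_days,
           boundary == "event" | .data$e + grace_days < .data$censor_at) |>
    arrange(.data$patient_id, .data$e) |>
    distinct(.data$patient_id, .keep_all = TRUE) |>
    select("patient_id", event_at = "e")

  out <- cens |>
    left_join(events, by = "patient_id") |>
    mutate(
      discontinued = !is.na(.data$event_at),
      t_end = if_else(.data$discontinued, .data$event_at, .data$censor_at),
      duration_days = pmax(.data$t_end - ws, 0)
    )

  # patients with no coverage at all in scope: immediate event
  no_cov <- !out$patient_id %in% timelines$patient_id
  if (any(no_cov)) {
    out$discontinued[no_cov] <- TRUE
    out$duration_days[no_cov] <- 0
  }

  out |>
    transmute(patient_id = .data$patient_id,
              duration_days = .data$duration_days,
              duration_months = .data$duration_days / DAYS_PER_MONTH,
              discontinued = .data$discontinued)
}

#' Kaplan-Meier persistence curve
#'
#' Product-limit estimate of the probability of remaining on therapy,
#' computed with [survival::survfit()].
#'
#' @param outcomes Output of [detect_discontinuation()].
#' @return An object of class `rxflow_km` wrapping the `survfit` fit; use
#'   [tidy()][generics::tidy] for the curve, [glance()][generics::glance]
#'   for summary statistics, and [ggplot2::autoplot()] to plot.
#' @export
kaplan_meier <- function(outcomes) {
  if (nrow(outcomes) == 0) abort("Need at least one persistence outcome.")
  fit <- survival::survfit(
    survival::Surv(duration_months, discontinued) ~ 1,
    data = outcomes
  )
  structure(list(fit = fit, outcomes = outcomes), class = "rxflow_km")
}

#' @export
print.rxflow_km <- function(x, ...) {
  g <- glance(x)
  cat("<rxflow_km> Kaplan-Meier persistence curve\n")
  cat(sprintf("  n = %d, events = %d\n", g$n, g$n_events))
  cat(sprintf("  S(12 months) = %.3f; mean observed duration = %.2f +/- %.2f months\n",
              g$persistence_12m, g$mean_duration_months, g$sd_duration_months))
  invisible(x)
}

#' Survival probability at given times
#'
#' @param km An `rxflow_km` object.
#' @param times Times in months.
#' @return Numeric vector of survival probabilities (right-continuous step
#'   function; times beyond the last observed time return the last value).
#' @export
km_survival_at <- function(km, times) {
  fit <- km$fit
  vapply(times, function(t) {
    idx <- which(fit$time <= t)
    if (!length(idx)) 1 else fit$surv[max(idx)]
  }, numeric(1))
}

#' Summarise persistence outcomes
#'
#' Reports the Kaplan-Meier persistence probability at a landmark time and
#' the arithmetic mean (+/- SD) of observed continuous-therapy durations.
#' The mean is taken over all patients, events and censored alike, with
#' censored durations window-truncated -- the "mean period of continuous
#' therapy" convention of claims-registry reports.
#'
#' @param outcomes Output of [detect_discontinuation()].
#' @param at_months Landmark time (default 12 months).
#' @return A one-row tibble: `n`, `n_events`, `persistence_at`,
#'   `mean_months`, `sd_months`.
#' @export
summarize_persistence <- function(outcomes, at_months = 12) {
  km <- kaplan_meier(outcomes)
  tibble(
    n = nrow(outcomes),
    n_events = sum(outcomes$discontinued),
    persistence_at = km_survival_at(km, at_months),
    mean_months = mean(outcomes$duration_months),
    sd_months = sd(outcomes$duration_months)
  )
}
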