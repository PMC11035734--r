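#' Medication Possession Ratio
#'
#' MPR is the proportion of days for which medication was supplied within
#' the patient's observation window. It is conventionally capped at 1:
#' possession beyond the window (stockpiled oversupply) does not count as
#' extra adherence. The uncapped value is kept by the cohort-level wrapper
#' as a diagnostic.
#'
#' @param covered_days Numeric vector of supplied days in the window.
#' @param window_days Numeric vector of window lengths in days (must be
#'   positive).
#' @param cap Cap the ratio at 1 (default `TRUE`).
#' @return Numeric vector of MPR values.
#' @examples
#' compute_mpr(60, 100)        # 0.6
#' compute_mpr(150, 100)       # 1 (capped)
#' @export
compute_mpr <- function(covered_days, window_days, cap = TRUE) {
  if (any(window_days <= 0)) {
    abort("`window_days` must be positive (degenerate observation window).")
  }
  mpr <- covered_days / window_days
  if (cap) mpr <- pmin(mpr, 1)
  mpr
}

#' Classify adherence at a possession threshold
#'
#' The threshold comparison is inclusive: a patient possessing medication
#' for exactly 80% of days is adherent at the 0.80 threshold ("MPR below
#' 0.80" defines non-adherence).
#'
#' @param mpr Numeric vector in `[0, 1]`.
#' @param threshold Possession threshold (default 0.80).
#' @return Logical vector.
#' @export
classify_adherent <- function(mpr, threshold = 0.80) {
  mpr >= threshold
}

#' Per-patient adherence records for a dispensation cohort
#'
#' For every patient with at least one dispensation in the window, computes
#' MPR over the patient's own analysis window: from the day of their first
#' statin dispensation until the study end, or their death if earlier
#' (therapy is assumed lifelong, so the intended treatment period runs to
#' the end of observation). Both window ends are inclusive days.
#'
#' @param dispensations Statin dispensation events.
#' @param patients Optional patient table supplying `death_date`.
#' @param window A [study_window()].
#' @param thresholds Possession thresholds to classify at (default 0.80 and
#'   0.90, reported as columns `adherent_80`, `adherent_90`).
#' @param cap Cap MPR at 1.
#' @param carryover Passed to [build_supply_timelines()].
#' @return A tibble with `patient_id`, `window_start`, `window_end`, `mpr`,
#'   `mpr_uncapped` and one logical column per threshold. Patients whose
#'   window would be degenerate (death on/before first dispensation) are
#'   excluded with a message.
#' @export
adherence_records <- function(dispensations, patients = NULL,
                              window = study_window(),
                              thresholds = c(0.80, 0.90), cap = TRUE,
                              carryover = TRUE) {
  window <- as_study_window(window)
  disp <- dispensations |>
    filter(.data$dispense_date >= window$start,
           .data$dispense_date <= window$end)
  if (nrow(disp) == 0) abort("No dispensations inside the window.")

  windows <- disp |>
    group_by(.data$patient_id) |>
    summarise(window_start = min(.data$dispense_date), .groups = "drop") |>
    mutate(window_end = window$end)
  if (!is.null(patients) && "death_date" %in% names(patients)) {
    windows <- windows |>
      left_join(select(patients, "patient_id", "death_date"),
                by = "patient_id") |>
      mutate(window_end = if_else(!is.na(.data$death_date) &
                                    .data$death_date < .data$window_end,
                                  .data$death_date, .data$window_end)) |>
      select(-"death_date")
    # a same-day death still leaves a 1-day window ([start, start + 1))
    degenerate <- windows$window_end < windows$window_start
    if (any(degenerate)) {
      inform(sprintf("%d patient(s) with death before first dispensation excluded",
                     sum(degenerate)))
      windows <- windows[!degenerate, ]
    }
  }

  timelines <- build_supply_timelines(disp, carryover = carryover)
  cov <- timelines |>
    inner_join(windows, by = "patient_id") |>
    mutate(ov = pmax(0, as.numeric(pmin(.data$end, .data$window_end + 1)) -
                        as.numeric(pmax(.data$start, .data$window_start))),
           supply = as.numeric(.data$end) - as.numeric(.data$start)) |>
    group_by(.data$patient_id) |>
    summarise(covered_days = sum(.data$ov),
              supply_days = sum(.data$supply), .groups = "drop")

  out <- windows |>
    left_join(cov, by = "patient_id") |>
    mutate(
      covered_days = coalesce(.data$covered_days, 0),
      supply_days = coalesce(.data$supply_days, 0),
      window_days = as.numeric(.data$window_end - .data$window_start) + 1,
      # capped MPR counts distinct covered days inside the window (the
      # PDC-style reading); the uncapped diagnostic relates all supply
      # received to the window and may exceed 1 under stockpiling
      mpr_uncapped = compute_mpr(.data$supply_days, .data$window_days,
                                 cap = FALSE),
      mpr = compute_mpr(.data$covered_days, .data$window_days, cap = cap)
    ) |>
    select("patient_id", "window_start", "window_end", "mpr", "mpr_uncapped")
  for (t in thresholds) {
    out[[sprintf("adherent_%02d", round(100 * t))]] <- classify_adherent(out$mpr, t)
  }
  out
}

#' Cohort-level adherence percentages
#'
#' @param records Output of [adherence_records()] (any tibble with an `mpr`
#'   column).
#' @param thresholds Possession thresholds.
#' @return A tibble with `threshold`, `n`, `n_adherent`, `pct_adherent`.
#' @export
cohort_adherence <- function(records, thresholds = c(0.80, 0.90)) {
  if (nrow(records) == 0) abort("Empty cohort.")
  purrr::map_dfr(thresholds, function(t) {
    adh <- classify_adherent(records$mpr, t)
    tibble(threshold = t, n = length(adh), n_adherent = sum(adh),
           pct_adherent = 100 * mean(adh))
  })
}
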