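#' Define the study observation window
#'
#' The default window runs from 2020-01-08 (the launch of the nationwide
#' e-prescription system, which makes the registry complete from that day on)
#' to 2022-12-31. All dates are calendar days; the window is inclusive on
#' both ends.
#'
#' @param start,end Dates (or strings coercible via [as.Date()]).
#' @return An object of class `study_window`: a list with elements `start`
#'   and `end`.
#' @examples
#' study_window()
#' study_window("2022-01-01", "2022-12-31")
#' @export
study_window <- function(start = "2020-01-08", end = "2022-12-31") {
  parse <- function(x) {
    tryCatch(as.Date(x), error = function(e) as.Date(NA))
  }
  start <- parse(start)
  end <- parse(end)
  if (is.na(start) || is.na(end)) {
    abort("`start` and `end` must be valid dates.")
  }
  if (start >= end) {
    abort("`start` must precede `end`.")
  }
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("<study_window> ", format(x$start), " .. ", format(x$end),
      " (", count_weeks(x), " ISO weeks)\n", sep = "")
  invisible(x)
}

as_study_window <- function(x) {
  if (inherits(x, "study_window")) return(x)
  if (length(x) == 2) return(study_window(x[[1]], x[[2]]))
  abort("Cannot interpret `window`; use `study_window()`.")
}

#' Enumerate the ISO weeks of a study window
#'
#' Builds the week calendar every weekly series in the package is keyed by:
#' one row per ISO-8601 week intersecting the window, from the week
#' containing the window start through the week containing the window end.
#' For the default window this yields 156 weeks (2020 contributes weeks
#' 2-53, 2021 and 2022 weeks 1-52).
#'
#' @param window A [study_window()].
#' @return A tibble with columns `iso_year`, `iso_week`, `week_start`
#'   (Monday of the ISO week) and a 0-based `week_index`.
#' @examples
#' iso_week_keys(study_window())
#' @export
iso_week_keys <- function(window = study_window()) {
  window <- as_study_window(window)
  days <- seq(window$start, window$end, by = "day")
  tibble(
    iso_year = lubridate::isoyear(days),
    iso_week = lubridate::isoweek(days),
    week_start = lubridate::floor_date(days, "week", week_start = 1)
  ) |>
    distinct(.data$iso_year, .data$iso_week, .data$week_start) |>
    arrange(.data$week_start) |>
    mutate(week_index = row_number() - 1L)
}

#' Count the ISO weeks intersecting a window
#'
#' @inheritParams iso_week_keys
#' @return Integer number of ISO weeks.
#' @examples
#' count_weeks(study_window()) # 156
#' @export
count_weeks <- function(window = study_window()) {
  nrow(iso_week_keys(window))
}

#' Polish population by calendar year
#'
#' Official national statistics (Statistics Poland), persons as of 31
#' December, used to express weekly tablet counts per 1000 inhabitants.
#'
#' @return A tibble with columns `year` and `population` (persons).
#' @examples
#' default_population()
#' @export
default_population <- function() {
  tibble(
    year = 2020:2022,
    population = c(38089000, 37908000, 37766000)
  )
}
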