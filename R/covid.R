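#' Lockdown calendar
#'
#' Lockdown periods are configured as inclusive ISO-week ranges rather than
#' derived from calendar dates: published week ranges are taken as the
#' authoritative input. The default reproduces the three Polish national
#' lockdowns of the study period -- weeks 12-22 and 46-52 of 2020 and weeks
#' 12-16 of 2021, 23 weeks in total.
#'
#' @param ranges A tibble (or data.frame) with columns `iso_year`,
#'   `week_from`, `week_to` (inclusive).
#' @return A tibble of class `lockdown_calendar`.
#' @export
lockdown_calendar <- function(ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- tibble(
      iso_year = c(2020L, 2020L, 2021L),
      week_from = c(12L, 46L, 12L),
      week_to = c(22L, 52L, 16L)
    )
  }
  ranges <- as_tibble(ranges)
  needed <- c("iso_year", "week_from", "week_to")
  if (!all(needed %in% names(ranges))) {
    abort("`ranges` needs columns iso_year, week_from, week_to.")
  }
  if (nrow(ranges) && any(ranges$week_from > ranges$week_to)) {
    abort("`week_from` must not exceed `week_to`.")
  }
  structure(ranges[needed], class = c("lockdown_calendar", class(ranges)))
}

is_lockdown_week <- function(iso_year, iso_week, calendar) {
  flag <- rep(FALSE, length(iso_year))
  for (k in seq_len(nrow(calendar))) {
    flag <- flag | (iso_year == calendar$iso_year[k] &
                      iso_week >= calendar$week_from[k] &
                      iso_week <= calendar$week_to[k])
  }
  flag
}

#' Flag lockdown weeks on a weekly series
#'
#' @param series A weekly series tibble (with `iso_year`, `iso_week`).
#' @param calendar A [lockdown_calendar()].
#' @return `series` with a logical `lockdown` column.
#' @examples
#' keys <- iso_week_keys(study_window())
#' sum(lockdown_flags(keys)$lockdown) # 23
#' @export
lockdown_flags <- function(series, calendar = lockdown_calendar()) {
  mutate(series,
         lockdown = is_lockdown_week(.data$iso_year, .data$iso_week, calendar))
}

#' Read a weekly COVID-19 series in the ECDC national-weekly dialect
#'
#' Expects columns `country,year_week,indicator,weekly_count` with
#' `year_week` as `YYYY-Www` and `indicator` values `cases` and `deaths`
#' (other indicators are skipped with a warning). The series is aligned to
#' the study week calendar; weeks missing from the file are filled with 0
#' and logged.
#'
#' @param path CSV path.
#' @param country Country to keep (default `"Poland"`).
#' @param window A [study_window()].
#' @return A tibble keyed like [iso_week_keys()] with `covid_cases` and
#'   `covid_deaths`; missing-week counts retrievable via [reader_log()].
#' @export
read_ecdc_weekly <- function(path, country = "Poland",
                             window = study_window()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("country", "year_week", "indicator", "weekly_count")
  if (!all(needed %in% names(raw))) {
    abort("Not an ECDC weekly file: need columns country, year_week, indicator, weekly_count.")
  }
  raw <- filter(raw, .data$country == !!country)
  unknown <- setdiff(unique(raw$indicator), c("cases", "deaths"))
  if (length(unknown)) {
    warn(paste0("Skipping unknown indicator(s): ",
                paste(unknown, collapse = ", ")))
    raw <- filter(raw, .data$indicator %in% c("cases", "deaths"))
  }
  parsed <- raw |>
    mutate(iso_year = as.integer(sub("-W.*$", "", .data$year_week)),
           iso_week = as.integer(sub("^.*-W", "", .data$year_week)),
           weekly_count = as.numeric(.data$weekly_count)) |>
    select("iso_year", "iso_week", "indicator", "weekly_count") |>
    tidyr::pivot_wider(names_from = "indicator",
                       values_from = "weekly_count",
                       values_fn = sum, values_fill = 0)
  for (cl in c("cases", "deaths")) {
    if (!cl %in% names(parsed)) parsed[[cl]] <- 0
  }
  keys <- iso_week_keys(window)
  out <- keys |>
    left_join(parsed, by = c("iso_year", "iso_week"))
  n_missing <- sum(is.na(out$cases) | is.na(out$deaths))
  out <- out |>
    mutate(covid_cases = as.integer(coalesce(.data$cases, 0)),
           covid_deaths = as.integer(coalesce(.data$deaths, 0))) |>
    select(-"cases", -"deaths")
  if (n_missing) {
    inform(sprintf("%d study week(s) missing from %s filled with 0",
                   n_missing, basename(path)))
  }
  rxflow_log(out, tibble(table = "covid_weekly", issue = "missing_week",
                         n = n_missing))
}

#' Correlate two weekly series
#'
#' Rank correlation (Spearman) by default, because weekly epidemic counts
#' are heavy-tailed; Pearson available by flag. P-values are two-sided and
#' computed without the exact permutation distribution (ties are routine
#' in count data).
#'
#' @param a,b Numeric vectors of equal length (>= 3 after removing pairs
#'   with missing values).
#' @param method `"spearman"` or `"pearson"`.
#' @return A one-row tibble: `method`, `n`, `estimate` (rho or r),
#'   `p_value`.
#' @export
correlate_series <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3) abort("Need at least 3 complete pairs.")
  ct <- suppressWarnings(cor.test(a[keep], b[keep], method = method,
                                  exact = FALSE))
  tibble(method = method, n = sum(keep),
         estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Compare lockdown and non-lockdown weeks of a series
#'
#' Reports group means, the relative deficit
#' `100 * (mean_other - mean_lockdown) / mean_other`, and a Mann-Whitney
#' rank test. This is the descriptive lockdown contrast on raw weekly
#' values; for recovering a configured lockdown effect net of secular
#' growth and seasonality, see [estimate_lockdown_deficit()].
#'
#' @param series A weekly series with a logical `lockdown` column (see
#'   [lockdown_flags()]).
#' @param value Column to compare (tidy-eval).
#' @return A one-row tibble: `n_lockdown`, `n_other`, `mean_lockdown`,
#'   `mean_other`, `percent_deficit`, `p_value`.
#' @export
compare_lockdown <- function(series, value) {
  df <- series |>
    mutate(v = {{ value }}) |>
    filter(!is.na(.data$v))
  if (!"lockdown" %in% names(df)) {
    abort("`series` needs a `lockdown` column; see lockdown_flags().")
  }
  a <- df$v[df$lockdown]
  b <- df$v[!df$lockdown]
  if (!length(a) || !length(b)) {
    abort("Both lockdown and non-lockdown groups must be non-empty.")
  }
  p <- if (length(unique(c(a, b))) == 1) 1 else
    suppressWarnings(wilcox.test(a, b)$p.value)
  tibble(
    n_lockdown = length(a), n_other = length(b),
    mean_lockdown = mean(a), mean_other = mean(b),
    percent_deficit = 100 * (mean(b) - mean(a)) / mean(b),
    p_value = p
  )
}

#' Estimate the lockdown effect net of trend and seasonality
#'
#' Interrupted-time-series style estimator: regresses the log weekly value
#' on a smooth time trend (quadratic in week index), week-of-year fixed
#' effects (ISO week 53 pooled with 52) and the lockdown flag. The
#' multiplicative lockdown effect is `exp(beta)`; the returned
#' `percent_deficit` is `100 * (1 - exp(beta))`. On a series generated
#' with a weekly intensity multiplier `m` in lockdown weeks this recovers
#' a deficit of `100 * (1 - m)` regardless of cohort growth or calendar
#' seasonality, which confound the raw two-group contrast of
#' [compare_lockdown()].
#'
#' @inheritParams compare_lockdown
#' @return A one-row tibble: `percent_deficit`, `multiplier`, `p_value`,
#'   `n`.
#' @export
estimate_lockdown_deficit <- function(series, value) {
  df <- series |>
    mutate(v = {{ value }}) |>
    filter(!is.na(.data$v), .data$v > 0)
  if (!"lockdown" %in% names(df)) {
    abort("`series` needs a `lockdown` column; see lockdown_flags().")
  }
  if (!any(df$lockdown) || all(df$lockdown)) {
    abort("Both lockdown and non-lockdown groups must be non-empty.")
  }
  df$woy <- factor(pmin(df$iso_week, 52))
  fit <- lm(log(v) ~ poly(week_index, 2) + woy + lockdown, data = df)
  sm <- summary(fit)$coefficients
  beta <- sm["lockdownTRUE", "Estimate"]
  tibble(
    percent_deficit = 100 * (1 - exp(beta)),
    multiplier = exp(beta),
    p_value = sm["lockdownTRUE", "Pr(>|t|)"],
    n = nrow(df)
  )
}

#' Compare lockdown weeks with the same-numbered weeks of an open year
#'
#' For each lockdown period, pairs its weekly values with the values of the
#' same ISO week numbers in a lockdown-free reference year and applies a
#' paired rank test. Week 53 of 2020 has no counterpart in a 52-week
#' reference year and is excluded with a warning.
#'
#' @param series A weekly series (with `iso_year`, `iso_week`).
#' @param value Column to compare (tidy-eval).
#' @param calendar A [lockdown_calendar()].
#' @param reference_year Lockdown-free comparison year (default 2022).
#' @return A tibble with one row per lockdown period: `period`,
#'   `iso_year`, `weeks`, `n_weeks`, `mean_lockdown`, `mean_reference`,
#'   `diff`, `p_value`.
#' @export
matched_week_comparison <- function(series, value,
                                    calendar = lockdown_calendar(),
                                    reference_year = 2022) {
  df <- mutate(series, v = {{ value }})
  ref <- filter(df, .data$iso_year == reference_year)
  purrr::map_dfr(seq_len(nrow(calendar)), function(k) {
    yr <- calendar$iso_year[k]
    weeks <- seq(calendar$week_from[k], calendar$week_to[k])
    drop <- setdiff(weeks, ref$iso_week)
    if (length(drop)) {
      warn(sprintf("week(s) %s of %d have no counterpart in %d; excluded",
                   paste(drop, collapse = ", "), yr, reference_year))
      weeks <- setdiff(weeks, drop)
    }
    lk <- df |>
      filter(.data$iso_year == yr, .data$iso_week %in% weeks) |>
      arrange(.data$iso_week)
    rf <- ref |>
      filter(.data$iso_week %in% weeks) |>
      arrange(.data$iso_week)
    d <- lk$v - rf$v
    p <- if (all(d == 0)) 1 else
      suppressWarnings(wilcox.test(lk$v, rf$v, paired = TRUE)$p.value)
    tibble(
      period = k, iso_year = yr,
      n_weeks = length(weeks),
      weeks = sprintf("%d-%d", calendar$week_from[k], calendar$week_to[k]),
      mean_lockdown = mean(lk$v), mean_reference = mean(rf$v),
      diff = mean(d), p_value = p
    )
  })
}
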