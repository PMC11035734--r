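#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Kaplan-Meier persistence curve
#'
#' @param x An `rxflow_km` object.
#' @param ... Unused.
#' @return A tibble with `time` (months), `n_risk`, `n_event`, `n_censor`,
#'   `survival`, `std_error`, `conf_low`, `conf_high`.
#' @export
tidy.rxflow_km <- function(x, ...) {
  f <- x$fit
  tibble(
    time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    n_censor = f$n.censor, survival = f$surv, std_error = f$std.err,
    conf_low = f$lower, conf_high = f$upper
  )
}

#' Summarise a Kaplan-Meier persistence curve
#'
#' @param x An `rxflow_km` object.
#' @param at_months Landmark persistence time (default 12).
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_events`, `persistence_12m` (or at
#'   `at_months`), `median_months`, `mean_duration_months`,
#'   `sd_duration_months`.
#' @export
glance.rxflow_km <- function(x, at_months = 12, ...) {
  med <- unname(summary(x$fit)$table["median"])
  tibble(
    n = nrow(x$outcomes),
    n_events = sum(x$outcomes$discontinued),
    persistence_12m = km_survival_at(x, at_months),
    median_months = med,
    mean_duration_months = mean(x$outcomes$duration_months),
    sd_duration_months = sd(x$outcomes$duration_months)
  )
}

#' Tidy a weekly trend fit
#'
#' @param x An `rxflow_trend` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`).
#' @export
tidy.rxflow_trend <- function(x, ...) {
  sm <- suppressWarnings(summary(x$model))$coefficients
  tibble(
    term = c("intercept", "week_index"),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
}

#' Summarise a weekly trend fit
#'
#' @param x An `rxflow_trend` object.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `p_value`, `fitted_first`,
#'   `fitted_last`, `pct_change`, `r_squared`, `n`.
#' @export
glance.rxflow_trend <- function(x, ...) {
  tibble(
    slope = x$slope,
    p_value = x$p_value,
    fitted_first = x$fitted_first,
    fitted_last = x$fitted_last,
    pct_change = percent_change_endpoints(x$fitted_first, x$fitted_last),
    r_squared = suppressWarnings(summary(x$model))$r.squared,
    n = x$n
  )
}

#' Tidy a between-year comparison
#'
#' @param x An `rxflow_year_comparison` object.
#' @param ... Unused.
#' @return The per-year `groups` tibble.
#' @export
tidy.rxflow_year_comparison <- function(x, ...) {
  x$groups
}

#' Summarise a between-year comparison
#'
#' @param x An `rxflow_year_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble: `statistic` (Kruskal-Wallis H), `df`,
#'   `p_value`, `normal`.
#' @export
glance.rxflow_year_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         normal = x$normal)
}
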