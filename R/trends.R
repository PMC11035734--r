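#' Aggregate claims events into a weekly utilisation series
#'
#' Sums tablets issued and tablets filled per ISO week of the study
#' calendar; each event counts in the week of its own date. Weeks without
#' events carry zeros, so the series always spans the full
#' [iso_week_keys()] calendar (156 weeks for the default window). Events
#' outside the window are excluded and counted in the attached
#' [reader_log()]-style attribute.
#'
#' @param prescriptions,dispensations Statin-filtered event tibbles.
#' @param window A [study_window()].
#' @return A weekly series tibble: `iso_year`, `iso_week`, `week_start`,
#'   `week_index`, `prescribed_tablets`, `dispensed_tablets`.
#' @export
aggregate_weekly <- function(prescriptions, dispensations,
                             window = study_window()) {
  window <- as_study_window(window)
  keys <- iso_week_keys(window)

  tally <- function(events, date_col, out_col) {
    dates <- events[[date_col]]
    inside <- dates >= window$start & dates <= window$end
    n_out <- sum(!inside)
    events <- events[inside, ]
    agg <- events |>
      mutate(iso_year = lubridate::isoyear(.data[[date_col]]),
             iso_week = lubridate::isoweek(.data[[date_col]])) |>
      group_by(.data$iso_year, .data$iso_week) |>
      summarise("{out_col}" := sum(as.numeric(.data$tablets)),
                .groups = "drop")
    list(agg = agg, n_out = n_out)
  }
  rx <- tally(prescriptions, "issue_date", "prescribed_tablets")
  dx <- tally(dispensations, "dispense_date", "dispensed_tablets")

  out <- keys |>
    left_join(rx$agg, by = c("iso_year", "iso_week")) |>
    left_join(dx$agg, by = c("iso_year", "iso_week")) |>
    mutate(prescribed_tablets = coalesce(.data$prescribed_tablets, 0),
           dispensed_tablets = coalesce(.data$dispensed_tablets, 0))
  rxflow_log(out, tibble(
    table = c("prescriptions", "dispensations"),
    issue = "outside_window",
    n = c(rx$n_out, dx$n_out)
  ))
}

#' Weekly percentage of tablets dispensed
#'
#' Adds `pct_dispensed = 100 * dispensed / prescribed` per week (the
#' same-week ratio). Weeks with nothing prescribed get `NA` and are
#' flagged. Note this contemporaneous ratio differs from the share of
#' issued tablets that is *ever* filled; see [overall_fill_percentage()]
#' for the aggregate version of the latter.
#'
#' @param series Output of [aggregate_weekly()].
#' @return `series` with columns `pct_dispensed` and `pct_undefined`.
#' @export
percent_dispensed <- function(series) {
  series |>
    mutate(pct_undefined = .data$prescribed_tablets <= 0,
           pct_dispensed = if_else(.data$pct_undefined, NA_real_,
                                   100 * .data$dispensed_tablets /
                                     .data$prescribed_tablets))
}

#' Overall fill percentage
#'
#' `100 * total dispensed / total prescribed` over the whole period.
#'
#' @param total_dispensed,total_prescribed Tablet totals.
#' @return Percentage (0-100 scale).
#' @examples
#' overall_fill_percentage(4010716658, 4681614262) # 85.67, i.e. ~86%
#' @export
overall_fill_percentage <- function(total_dispensed, total_prescribed) {
  if (any(total_prescribed <= 0)) abort("`total_prescribed` must be positive.")
  100 * total_dispensed / total_prescribed
}

#' Weekly tablets per 1000 inhabitants
#'
#' Divides weekly counts by the population (in thousands) of the week's
#' ISO year.
#'
#' @param series A weekly series with `iso_year` and tablet columns.
#' @param population A tibble like [default_population()] (`year`,
#'   `population` in persons).
#' @param cols Columns to normalise.
#' @return `series` with added `<col>_per_1000` columns.
#' @export
per_capita_rate <- function(series, population = default_population(),
                            cols = c("prescribed_tablets",
                                     "dispensed_tablets")) {
  missing_years <- setdiff(unique(series$iso_year), population$year)
  if (length(missing_years)) {
    abort(paste0("No population for year(s): ",
                 paste(missing_years, collapse = ", ")))
  }
  out <- series |>
    left_join(population, by = c(iso_year = "year"))
  for (cl in cols) {
    out[[paste0(cl, "_per_1000")]] <- out[[cl]] / (out$population / 1000)
  }
  select(out, -"population")
}

#' Ordinary least-squares trend of a weekly series
#'
#' Fits `value ~ week_index` (index 0, 1, ...) and reports the weekly
#' slope, the fitted values at the first and last week, and the two-sided
#' significance of the slope. On exactly linear data the slope is recovered
#' to machine precision.
#'
#' @param series A weekly series tibble.
#' @param value Column to fit (tidy-eval).
#' @return An object of class `rxflow_trend`; see
#'   [tidy()][generics::tidy] / [glance()][generics::glance]. Fields
#'   include `slope`, `p_value`, `fitted_first`, `fitted_last`.
#' @export
fit_linear_trend <- function(series, value) {
  v <- pull(series, {{ value }})
  keep <- !is.na(v)
  if (sum(keep) < 3) abort("Need at least 3 non-missing points.")
  idx <- series$week_index[keep]
  fit <- lm(v[keep] ~ idx)
  # exact linear input triggers a harmless perfect-fit note in summary.lm
  sm <- suppressWarnings(summary(fit))
  new_idx <- range(series$week_index)
  fitted_ends <- unname(coef(fit)[1] + coef(fit)[2] * new_idx)
  structure(list(
    model = fit,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = sm$coefficients["idx", "Pr(>|t|)"],
    fitted_first = fitted_ends[1],
    fitted_last = fitted_ends[2],
    n = sum(keep)
  ), class = "rxflow_trend")
}

#' @export
print.rxflow_trend <- function(x, ...) {
  cat("<rxflow_trend> OLS weekly trend\n")
  cat(sprintf("  slope = %.5g per week (p = %.3g), fitted %0.4g -> %0.4g over %d weeks\n",
              x$slope, x$p_value, x$fitted_first, x$fitted_last, x$n))
  invisible(x)
}

#' Percent change between trend endpoints
#'
#' `100 * (last - first) / first`, reported to one decimal -- the
#' convention for endpoint changes of fitted utilisation trends.
#'
#' @param first,last Endpoint values (`first` must be positive).
#' @param digits Decimals to report (default 1).
#' @return Percentage change.
#' @examples
#' percent_change_endpoints(27418954, 32601689) # 18.9
#' @export
percent_change_endpoints <- function(first, last, digits = 1) {
  if (any(first <= 0)) abort("`first` must be positive.")
  round(100 * (last - first) / first, digits)
}

iso_quarter <- function(iso_week) {
  pmin((iso_week - 1) %/% 13 + 1, 4)
}

#' Quarterly summaries of a weekly percentage series
#'
#' Maps ISO weeks to calendar quarters (weeks 1-13, 14-26, 27-39, 40-end)
#' and pools weekly values across study years.
#'
#' @param series A weekly series tibble.
#' @param value Column to summarise (tidy-eval; typically `pct_dispensed`).
#' @return A tibble with `quarter`, `n_weeks`, `mean`, `sd`.
#' @export
aggregate_quarters <- function(series, value) {
  series |>
    mutate(quarter = iso_quarter(.data$iso_week)) |>
    group_by(.data$quarter) |>
    summarise(n_weeks = sum(!is.na({{ value }})),
              mean = mean({{ value }}, na.rm = TRUE),
              sd = sd({{ value }}, na.rm = TRUE),
              .groups = "drop")
}

#' Pairwise quarter comparisons
#'
#' Rank-based (Mann-Whitney) tests between all quarter pairs of pooled
#' weekly values, without multiple-testing correction (single-comparison
#' p-values are reported as such).
#'
#' @inheritParams aggregate_quarters
#' @return A tibble with `quarter_a`, `quarter_b`, means, `diff` and
#'   `p_value`.
#' @export
compare_quarters <- function(series, value) {
  df <- series |>
    mutate(quarter = iso_quarter(.data$iso_week),
           v = {{ value }}) |>
    filter(!is.na(.data$v))
  pairs <- utils::combn(sort(unique(df$quarter)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- df$v[df$quarter == pairs[1, k]]
    b <- df$v[df$quarter == pairs[2, k]]
    p <- if (length(unique(c(a, b))) == 1) 1 else
      suppressWarnings(wilcox.test(a, b)$p.value)
    tibble(quarter_a = pairs[1, k], quarter_b = pairs[2, k],
           mean_a = mean(a), mean_b = mean(b),
           diff = mean(b) - mean(a), p_value = p)
  })
}

#' Compare a weekly percentage between calendar years
#'
#' Kruskal-Wallis test across the ISO years of the series, preceded by a
#' per-year Shapiro-Wilk normality check that decides whether means or
#' medians are the appropriate location summary to report alongside.
#'
#' @inheritParams aggregate_quarters
#' @return A list of class `rxflow_year_comparison`: `statistic` (H), `df`,
#'   `p_value`, `normal` (all groups pass Shapiro-Wilk at 0.05), and a
#'   `groups` tibble with per-year n, mean, sd, median and Shapiro p.
#' @export
compare_years <- function(series, value) {
  df <- series |>
    mutate(v = {{ value }}) |>
    filter(!is.na(.data$v))
  groups <- split(df$v, df$iso_year)
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("Need >= 2 years with >= 2 values each.")
  }
  kw <- if (length(unique(df$v)) == 1) {
    # fully degenerate input: no rank variation, no evidence of difference
    list(statistic = 0, parameter = length(groups) - 1L, p.value = 1)
  } else {
    suppressWarnings(kruskal.test(df$v, factor(df$iso_year)))
  }
  gr <- purrr::imap_dfr(groups, function(v, y) {
    sw <- if (length(unique(v)) > 2) shapiro.test(v)$p.value else NA_real_
    tibble(iso_year = as.integer(y), n = length(v), mean = mean(v),
           sd = sd(v), median = median(v), shapiro_p = sw)
  })
  structure(list(
    statistic = unname(kw$statistic),
    df = unname(kw$parameter),
    p_value = kw$p.value,
    normal = all(gr$shapiro_p > 0.05, na.rm = TRUE),
    groups = gr
  ), class = "rxflow_year_comparison")
}

#' @export
print.rxflow_year_comparison <- function(x, ...) {
  cat("<rxflow_year_comparison> Kruskal-Wallis across years\n")
  cat(sprintf("  H = %.3f (df = %d), p = %.3g; location summary: %s\n",
              x$statistic, x$df, x$p_value,
              if (x$normal) "means (normality not rejected)" else
                "medians (normality rejected)"))
  print(x$groups)
  invisible(x)
}
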