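shade_lockdowns <- function(series) {
  if (!"lockdown" %in% names(series) || !any(series$lockdown)) return(NULL)
  runs <- series |>
    arrange(.data$week_index) |>
    mutate(block = cumsum(.data$lockdown != lag(.data$lockdown,
                                                default = FALSE))) |>
    filter(.data$lockdown) |>
    group_by(.data$block) |>
    summarise(xmin = min(.data$week_start),
              xmax = max(.data$week_start) + 7, .groups = "drop")
  ggplot2::geom_rect(
    data = runs,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                 ymin = -Inf, ymax = Inf),
    inherit.aes = FALSE, fill = "firebrick", alpha = 0.12
  )
}

#' Plot weekly prescribed and dispensed tablets
#'
#' Line chart of the two weekly tablet series with dotted OLS trend lines
#' and lockdown weeks shaded.
#'
#' @param series A weekly series (see [aggregate_weekly()]), ideally with a
#'   `lockdown` column.
#' @return A ggplot object.
#' @export
plot_weekly_series <- function(series) {
  long <- series |>
    select("week_start", "week_index", "prescribed_tablets",
           "dispensed_tablets") |>
    tidyr::pivot_longer(c("prescribed_tablets", "dispensed_tablets"),
                        names_to = "series", values_to = "tablets") |>
    mutate(series = ifelse(.data$series == "prescribed_tablets",
                           "prescribed", "dispensed"))
  ggplot2::ggplot(long, ggplot2::aes(.data$week_start, .data$tablets,
                                     colour = .data$series)) +
    shade_lockdowns(series) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linetype = "dotted", linewidth = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) format(x, big.mark = ",",
                                                            scientific = FALSE)) +
    ggplot2::labs(x = NULL, y = "tablets per week", colour = NULL,
                  title = "Weekly statin tablets prescribed and dispensed") +
    ggplot2::theme_minimal()
}

#' Plot the weekly percentage of tablets dispensed
#'
#' @param series A weekly series with `pct_dispensed` (see
#'   [percent_dispensed()]).
#' @return A ggplot object.
#' @export
plot_percent_dispensed <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(.data$week_start,
                                       .data$pct_dispensed)) +
    shade_lockdowns(series) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = mean(series$pct_dispensed, na.rm = TRUE),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = NULL, y = "% of prescribed tablets dispensed",
                  title = "Weekly dispensation percentage") +
    ggplot2::theme_minimal()
}

#' Plot weekly COVID-19 counts against the dispensation percentage
#'
#' Case and death counts on the count scale with the weekly dispensation
#' percentage overlaid (rescaled, for shape comparison only) and lockdown
#' weeks shaded.
#'
#' @param series A weekly series with `covid_cases`, `covid_deaths` and
#'   `pct_dispensed`.
#' @return A ggplot object.
#' @export
plot_covid_overlay <- function(series) {
  scale_to <- max(series$covid_cases, na.rm = TRUE)
  rng <- range(series$pct_dispensed, na.rm = TRUE)
  overlay <- series |>
    mutate(pct_scaled = scale_to * (.data$pct_dispensed - rng[1]) /
             max(rng[2] - rng[1], 1e-9))
  ggplot2::ggplot(series, ggplot2::aes(.data$week_start)) +
    shade_lockdowns(series) +
    ggplot2::geom_col(ggplot2::aes(y = .data$covid_cases),
                      fill = "grey70", width = 7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$covid_deaths * 50),
                       colour = "black") +
    ggplot2::geom_line(data = overlay,
                       ggplot2::aes(y = .data$pct_scaled),
                       colour = "steelblue", linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "weekly COVID-19 cases (deaths x 50)",
                  title = "COVID-19 dynamics and statin dispensation",
                  subtitle = "dotted: % dispensed, rescaled (shape only)") +
    ggplot2::theme_minimal()
}

#' Plot a Kaplan-Meier persistence curve
#'
#' @param object An `rxflow_km` object.
#' @param ... Unused.
#' @return A ggplot object (step curve with confidence band).
#' @export
autoplot.rxflow_km <- function(object, ...) {
  df <- tidy(object)
  df0 <- bind_rows(tibble(time = 0, survival = 1, conf_low = 1,
                          conf_high = 1), df)
  ggplot2::ggplot(df0, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dotted",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = "dotted",
                       colour = "grey50", na.rm = TRUE) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "months since baseline", y = "persistence",
                  title = "Kaplan-Meier persistence with statin therapy") +
    ggplot2::theme_minimal()
}
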