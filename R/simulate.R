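#' Parameters of the synthetic claims cohort
#'
#' Bundles and validates every tunable of [simulate_cohort()]. Defaults are
#' calibrated so that the downstream pipeline, run on a generated registry,
#' reproduces the aggregate behaviour of national statin claims: an 86%
#' fill fraction, roughly 40% twelve-month persistence, a 6.8% prescribing
#' deficit in lockdown weeks (with a 5.9% dispensing deficit), a year-end
#' prescribing trough with a new-year rebound, and a slow secular growth in
#' prescribing volume.
#'
#' @param n_patients Cohort size.
#' @param prevalent_frac Fraction of patients already on therapy when the
#'   window opens; the rest initiate during the window with intensity
#'   proportional to the weekly multipliers.
#' @param pack_mix Named numeric vector: tablets per prescription and their
#'   probabilities (names are tablet counts; weights must sum to 1).
#' @param p_never_dispensed Probability a prescription is never filled
#'   (primary non-adherence).
#' @param renewal_gap_mean,renewal_gap_shape Gamma-distributed gap (days)
#'   until a replacement prescription is issued after one expires unfilled;
#'   the tight default (mean 7, shape 16) reflects how quickly an expired
#'   e-prescription is reissued.
#' @param dispense_delay_prob Success probability of the geometric
#'   issue-to-fill delay (mean delay `(1 - p) / p` days).
#' @param refill_lead_mean,refill_lead_shape Lead time (days) by which the
#'   next prescription is issued *before* current supply runs out. The
#'   magnitude is gamma-distributed with the given shape; a negative mean
#'   flips the sign and models habitual late refills.
#' @param monthly_stop_hazard Constant hazard (per 30.4375-day month) of
#'   permanently stopping therapy. The default 0.0764 gives closed-form
#'   12-month persistence `exp(-12 * 0.0764) = 0.40`.
#' @param annual_death_prob Annual probability of death.
#' @param seasonal_multipliers Numeric vector of length 53: multiplicative
#'   effect of each ISO week on prescribing intensity.
#' @param lockdown_multiplier_rx Multiplier on prescribing intensity during
#'   lockdown weeks.
#' @param lockdown_multiplier_disp Target multiplier on dispensing volume
#'   during lockdown weeks; implemented as a lockdown-time change in fill
#'   probability `(1 - p_never_dispensed) * disp / rx`, so the dispensing
#'   deficit is smaller than the prescribing deficit and the percentage
#'   dispensed rises slightly in lockdown.
#' @param weekly_trend Weekly multiplicative growth of initiation
#'   intensity; the default compounds to +18.9% over the 155 week-on-week
#'   steps of the default window.
#' @param atc_mix Named probabilities of ATC codes assigned to
#'   prescriptions.
#' @param p_female,p_male Sex distribution (remainder recorded as missing).
#' @param birth_year_mean,birth_year_sd Patient birth-year distribution.
#' @return A validated list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 10000,
                          prevalent_frac = 0.25,
                          pack_mix = c("28" = 0.30, "30" = 0.45,
                                       "56" = 0.05, "60" = 0.15,
                                       "84" = 0.02, "90" = 0.03),
                          p_never_dispensed = 0.14,
                          renewal_gap_mean = 7,
                          renewal_gap_shape = 16,
                          dispense_delay_prob = 1 / 3,
                          refill_lead_mean = 10,
                          refill_lead_shape = 4,
                          monthly_stop_hazard = 0.0764,
                          annual_death_prob = 0.033,
                          seasonal_multipliers = default_seasonality(),
                          lockdown_multiplier_rx = 0.932,
                          lockdown_multiplier_disp = 0.941,
                          weekly_trend = 1.189^(1 / 155),
                          atc_mix = c("C10AA01" = 0.25, "C10AA05" = 0.45,
                                      "C10AA07" = 0.25, "C10BA02" = 0.03,
                                      "C10BA05" = 0.02),
                          p_female = 0.554,
                          p_male = 0.444,
                          birth_year_mean = 1955,
                          birth_year_sd = 12) {
  p <- as.list(environment())
  probs <- c(p$p_never_dispensed, p$dispense_delay_prob, p$annual_death_prob,
             p$p_female, p$p_male, p$prevalent_frac)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (p$p_female + p$p_male > 1) abort("p_female + p_male must not exceed 1.")
  if (abs(sum(p$pack_mix) - 1) > 1e-8) abort("`pack_mix` weights must sum to 1.")
  if (any(as.numeric(names(p$pack_mix)) < 1)) abort("Pack sizes must be >= 1 tablet.")
  if (abs(sum(p$atc_mix) - 1) > 1e-8) abort("`atc_mix` weights must sum to 1.")
  if (p$monthly_stop_hazard < 0) abort("`monthly_stop_hazard` must be >= 0.")
  if (p$renewal_gap_mean <= 0 || p$renewal_gap_shape <= 0 ||
      p$refill_lead_shape <= 0) {
    abort("Renewal gap and refill lead parameters must be positive.")
  }
  if (p$dispense_delay_prob <= 0) abort("`dispense_delay_prob` must be in (0, 1].")
  if (length(p$seasonal_multipliers) != 53 || any(p$seasonal_multipliers <= 0)) {
    abort("`seasonal_multipliers` must be 53 positive values (ISO weeks 1-53).")
  }
  if (p$lockdown_multiplier_rx <= 0 || p$lockdown_multiplier_disp <= 0 ||
      p$weekly_trend <= 0) {
    abort("Multipliers must be positive.")
  }
  if (p$n_patients < 1) abort("`n_patients` must be >= 1.")
  structure(p, class = "cohort_params")
}

#' Default weekly seasonality of prescribing intensity
#'
#' A year-end trough (weeks 51-53 at 0.75) followed by a new-year rebound
#' (weeks 1-2 at 1.15), flat elsewhere -- the repeatable holiday pattern of
#' national prescribing series.
#'
#' @return Numeric vector of length 53, indexed by ISO week.
#' @export
default_seasonality <- function() {
  m <- rep(1, 53)
  m[51:53] <- 0.75
  m[1:2] <- 1.15
  m
}

#' Simulate a synthetic prescription/dispensation registry
#'
#' Generates a cohort of statin users with realistic claims structure. Each
#' patient's refills are anchored to supply exhaustion: the next
#' prescription is issued around `refill_lead_mean` days before the current
#' stock runs out. Prescriptions expire unfilled with probability
#' `p_never_dispensed`, in which case a replacement is sought after a short
#' renewal gap. Calendar effects (seasonality and lockdowns) stretch or
#' compress refill timing locally through an operational-time warp, so the
#' weekly event intensity is proportional to the configured multipliers
#' while each episode self-corrects afterwards (patients catch up on
#' postponed refills). The secular trend acts on initiation intensity only,
#' i.e. utilisation grows through cohort turnover, not through established
#' patients collecting surplus stock.
#'
#' Therapy stops permanently through per-refill decisions carrying a
#' constant hazard on the supply-exhaustion timescale, so the
#' claims-visible discontinuation (the final exhaustion date) is itself an
#' exponential stopping time with the configured monthly hazard; death
#' censors everything. The generator is fully reproducible from `seed` and
#' uses no global random state.
#'
#' @param params A [cohort_params()] object.
#' @param window A [study_window()].
#' @param seed Integer seed.
#' @param lockdowns A [lockdown_calendar()] defining lockdown weeks.
#' @return A list with tibbles `patients`, `prescriptions`,
#'   `dispensations` matching the [registry] schemas.
#' @export
simulate_cohort <- function(params = cohort_params(),
                            window = study_window(),
                            seed = 1L,
                            lockdowns = lockdown_calendar()) {
  stopifnot(inherits(params, "cohort_params"))
  window <- as_study_window(window)
  withr::with_seed(as.integer(seed), simulate_cohort_impl(params, window, lockdowns))
}

simulate_cohort_impl <- function(params, window, lockdowns) {
  days <- seq(window$start, window$end, by = "day")
  nd <- length(days)
  iso_w <- lubridate::isoweek(days)
  iso_y <- lubridate::isoyear(days)
  lock_day <- is_lockdown_week(iso_y, iso_w, lockdowns)

  m_season <- params$seasonal_multipliers[iso_w]
  m_refill <- m_season * ifelse(lock_day, params$lockdown_multiplier_rx, 1)
  week_idx <- as.numeric(days - days[1]) / 7
  m_init <- m_refill * params$weekly_trend^week_idx
  C <- cumsum(m_refill)
  p_fill_day <- pmin(1, (1 - params$p_never_dispensed) *
                       ifelse(lock_day,
                              params$lockdown_multiplier_disp /
                                params$lockdown_multiplier_rx, 1))

  n <- params$n_patients
  n_prev <- round(n * params$prevalent_frac)
  pack_sizes <- as.numeric(names(params$pack_mix))
  mean_pack <- sum(pack_sizes * params$pack_mix)

  # first in-window prescription day
  init_idx <- integer(n)
  if (n_prev > 0) {
    # stationary phase for established users: the time to their first
    # in-window refill is the forward-recurrence time of the renewal
    # process -- a uniform position inside a length-biased refill cycle.
    # This keeps the aggregate weekly refill rate flat from day one
    # instead of producing cohort-wide echo waves.
    cyc <- pack_sizes[sample.int(length(pack_sizes), n_prev, replace = TRUE,
                                 prob = pack_sizes * params$pack_mix /
                                   sum(pack_sizes * params$pack_mix))]
    init_idx[seq_len(n_prev)] <-
      1L + floor(runif(n_prev) * (cyc + max(0, -params$refill_lead_mean)))
  }
  if (n > n_prev) {
    init_idx[(n_prev + 1):n] <- sample.int(nd, n - n_prev, replace = TRUE,
                                           prob = m_init)
  }

  stop_rate <- params$monthly_stop_hazard / DAYS_PER_MONTH
  death_rate <- -log(1 - params$annual_death_prob) / 365.25
  # mortality clock runs from cohort entry: the window start for
  # established users, the initiation date for incident users (otherwise
  # late initiators would be selectively removed before entering,
  # flattening the realized initiation trend)
  death_idx <- if (death_rate > 0) {
    ifelse(seq_len(n) <= n_prev, 1, init_idx) + rexp(n, death_rate)
  } else {
    rep(Inf, n)
  }

  patient_id <- sprintf("P%06d", seq_len(n))
  sex <- sample(c("F", "M", "missing"), n, replace = TRUE,
                prob = c(params$p_female, params$p_male,
                         max(0, 1 - params$p_female - params$p_male)))
  birth_year <- as.integer(round(rnorm(n, params$birth_year_mean,
                                       params$birth_year_sd)))
  patients <- tibble(
    patient_id = patient_id,
    sex = sex,
    birth_year = birth_year,
    death_date = if_else(death_idx <= nd, days[pmin(floor(death_idx), nd)],
                         as.Date(NA))
  )

  # vectorised cycle loop over all still-active patients. Therapy stops by
  # per-refill decisions: when a fill advances the supply-exhaustion date
  # from e_prev to e, the patient stops renewing with probability
  # 1 - exp(-hazard * (e - e_prev)), so the claims-visible discontinuation
  # (the final exhaustion) carries exactly the configured constant hazard
  # on the exhaustion timescale.
  cur <- init_idx
  exhaust <- as.numeric(init_idx) # no stock before the first in-window fill
  prev_exhaust <- exhaust
  limit <- pmin(death_idx, nd)
  active <- cur <= limit
  rx_pid <- rx_day <- rx_tab <- list()
  dx_pid <- dx_day <- dx_tab <- dx_ord <- list()
  cycle <- 0L
  while (any(active)) {
    cycle <- cycle + 1L
    i <- which(active)
    d <- cur[i]
    tab <- pack_sizes[sample.int(length(pack_sizes), length(i),
                                 replace = TRUE, prob = params$pack_mix)]
    filled <- runif(length(i)) < p_fill_day[d]
    delay <- rgeom(length(i), params$dispense_delay_prob)
    disp_day <- d + delay
    rec <- filled & disp_day <= pmin(nd, death_idx[i])
    rx_pid[[cycle]] <- i
    rx_day[[cycle]] <- d
    rx_tab[[cycle]] <- tab
    dx_pid[[cycle]] <- i[rec]
    dx_day[[cycle]] <- disp_day[rec]
    dx_tab[[cycle]] <- tab[rec]
    dx_ord[[cycle]] <- which(rec) # cycle-local index into rx records

    # supply accrues whenever the fill happened, recorded or not
    fi <- i[filled]
    prev_exhaust[fi] <- exhaust[fi]
    exhaust[fi] <- pmax(disp_day[filled], exhaust[fi]) + tab[filled]

    # stopping decision for this completed exhaustion interval
    keep_going <- rep(TRUE, length(i))
    if (stop_rate > 0 && any(filled)) {
      keep_going[filled] <- runif(sum(filled)) <
        exp(-stop_rate * (exhaust[fi] - prev_exhaust[fi]))
    }

    lead <- if (params$refill_lead_mean == 0) {
      numeric(length(i))
    } else {
      sign(params$refill_lead_mean) *
        stats::rgamma(length(i), shape = params$refill_lead_shape,
                      rate = params$refill_lead_shape /
                        abs(params$refill_lead_mean))
    }
    g_fill <- pmax(1, exhaust[i] - lead - d)
    g_miss <- pmax(1, stats::rgamma(length(i), shape = params$renewal_gap_shape,
                                    rate = params$renewal_gap_shape /
                                      params$renewal_gap_mean))
    g <- ifelse(filled, g_fill, g_miss)
    nxt <- findInterval(C[d] + g - 1e-9, C) + 1L
    nxt <- pmax(nxt, d + 1L)
    cur[i] <- nxt
    active[i] <- keep_going & nxt <= limit[i]
    if (cycle > 2000) abort("Simulation failed to terminate.") # safety net
  }

  ord <- order(unlist(rx_day), unlist(rx_pid))
  rx_n <- length(ord)
  rx_key <- integer(rx_n)
  rx_key[ord] <- seq_len(rx_n)
  prescriptions <- tibble(
    prescription_id = sprintf("R%08d", rx_key),
    patient_id = patient_id[unlist(rx_pid)],
    issue_date = days[unlist(rx_day)],
    atc_code = sample(names(params$atc_mix), rx_n, replace = TRUE,
                      prob = params$atc_mix),
    tablets = as.integer(unlist(rx_tab))
  )[ord, ]

  # map dispensations back to their prescription ids
  offs <- cumsum(c(0L, vapply(rx_pid, length, integer(1))))
  dx_global <- unlist(purrr::map2(dx_ord, seq_along(dx_ord),
                                  function(loc, k) offs[k] + loc))
  dispensations <- tibble(
    prescription_id = sprintf("R%08d", rx_key[dx_global]),
    patient_id = patient_id[unlist(dx_pid)],
    dispense_date = days[unlist(dx_day)],
    tablets = as.integer(unlist(dx_tab))
  ) |>
    arrange(.data$dispense_date, .data$prescription_id)

  list(patients = patients, prescriptions = prescriptions,
       dispensations = dispensations)
}

#' Parameters of the synthetic weekly COVID-19 series
#'
#' Phenomenological epidemic waves: weekly case counts are a sum of
#' Gaussian bumps with negative-binomial noise; weekly deaths are a lagged
#' fraction of cases with their own noise. No transmission mechanism is
#' modelled.
#'
#' @param wave_center Week indices (0-based, on the study calendar) of wave
#'   peaks.
#' @param wave_width Wave widths in weeks (Gaussian SD).
#' @param wave_height Peak weekly case counts.
#' @param case_fatality Ratio of weekly deaths to lagged weekly cases.
#' @param lag_weeks Lag between the case wave and the death wave.
#' @param dispersion Negative-binomial size parameter; 0 disables noise
#'   (deterministic rounded means).
#' @return A validated list of class `covid_params`.
#' @export
covid_params <- function(wave_center = c(12, 45, 63, 105),
                         wave_width = c(4, 5, 5, 4),
                         wave_height = c(5000, 150000, 180000, 220000),
                         case_fatality = 0.02,
                         lag_weeks = 2,
                         dispersion = 50) {
  if (length(wave_center) != length(wave_width) ||
      length(wave_center) != length(wave_height)) {
    abort("Wave parameter vectors must have equal length.")
  }
  if (any(wave_width <= 0) || any(wave_height < 0)) {
    abort("Wave widths must be positive and heights non-negative.")
  }
  if (case_fatality < 0 || case_fatality > 1) {
    abort("`case_fatality` must lie in [0, 1].")
  }
  if (lag_weeks < 0 || dispersion < 0) {
    abort("`lag_weeks` and `dispersion` must be non-negative.")
  }
  structure(list(wave_center = wave_center, wave_width = wave_width,
                 wave_height = wave_height, case_fatality = case_fatality,
                 lag_weeks = lag_weeks, dispersion = dispersion),
            class = "covid_params")
}

#' Simulate weekly COVID-19 cases and deaths
#'
#' @param params A [covid_params()] object.
#' @param window A [study_window()].
#' @param seed Integer seed.
#' @return A tibble keyed like [iso_week_keys()] with integer columns
#'   `covid_cases` and `covid_deaths` (non-negative).
#' @export
simulate_covid_series <- function(params = covid_params(),
                                  window = study_window(),
                                  seed = 1L) {
  stopifnot(inherits(params, "covid_params"))
  keys <- iso_week_keys(window)
  t <- keys$week_index
  mu <- rep(0, length(t))
  for (j in seq_along(params$wave_center)) {
    mu <- mu + params$wave_height[j] *
      exp(-(t - params$wave_center[j])^2 / (2 * params$wave_width[j]^2))
  }
  withr::with_seed(as.integer(seed), {
    cases <- if (params$dispersion > 0) {
      rnbinom(length(mu), size = params$dispersion, mu = mu)
    } else {
      round(mu)
    }
    mu_d <- params$case_fatality *
      dplyr::lag(cases, params$lag_weeks, default = 0)
    deaths <- if (params$dispersion > 0) {
      rnbinom(length(mu_d), size = params$dispersion, mu = mu_d)
    } else {
      round(mu_d)
    }
    keys |>
      mutate(covid_cases = as.integer(cases),
             covid_deaths = as.integer(deaths))
  })
}

#' Write a weekly COVID series in the ECDC national-weekly CSV dialect
#'
#' Long format with columns `country,year_week,indicator,weekly_count`,
#' `year_week` as `YYYY-Www` and `indicator` in `cases` / `deaths` -- the
#' layout of the public ECDC weekly surveillance export.
#'
#' @param series Output of [simulate_covid_series()] (or any tibble with
#'   `iso_year`, `iso_week`, `covid_cases`, `covid_deaths`).
#' @param path Output CSV path.
#' @param country Country label.
#' @return Invisibly, `path`.
#' @seealso [read_ecdc_weekly()]
#' @export
write_covid_weekly <- function(series, path, country = "Poland") {
  long <- bind_rows(
    series |>
      transmute(country = country,
                year_week = sprintf("%d-W%02d", .data$iso_year, .data$iso_week),
                indicator = "cases", weekly_count = .data$covid_cases),
    series |>
      transmute(country = country,
                year_week = sprintf("%d-W%02d", .data$iso_year, .data$iso_week),
                indicator = "deaths", weekly_count = .data$covid_deaths)
  )
  readr::write_csv(long, path)
  invisible(path)
}
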