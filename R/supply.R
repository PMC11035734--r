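#' Convert tablet counts to standard-pack equivalents
#'
#' Tablet totals are standardised to 30-tablet packs, the conventional unit
#' for reporting national utilisation. Rounding is half away from zero, so
#' printed national pack counts are reproduced exactly from tablet totals.
#'
#' @param tablets Non-negative numeric vector of tablet counts.
#' @param pack_size Tablets per standard pack (default 30).
#' @return Pack counts, rounded to the nearest integer.
#' @examples
#' tablets_to_packs(4681614262) # 156053809
#' tablets_to_packs(45)         # 2 (half away from zero)
#' @export
tablets_to_packs <- function(tablets, pack_size = 30) {
  if (!is.numeric(pack_size) || length(pack_size) != 1 || pack_size <= 0) {
    abort("`pack_size` must be a single positive number.")
  }
  if (any(tablets < 0, na.rm = TRUE)) {
    abort("`tablets` must be non-negative.")
  }
  x <- tablets / pack_size
  sign(x) * floor(abs(x) + 0.5)
}

#' Build per-patient medication supply timelines
#'
#' Converts dispensation events into disjoint half-open coverage intervals
#' `[start, end)` of days on which the patient holds medication, at a fixed
#' daily dose (one tablet per day by default, all retained products being
#' interchangeable). A dispensation on day `d` covers `d` itself.
#'
#' With `carryover = TRUE` (the default), supply dispensed before the
#' previous fill has run out is stockpiled: each event adds
#' `tablets / dose_per_day` days of coverage starting at the later of its
#' dispense date and the current exhaustion date. Early refills therefore
#' extend coverage contiguously; late refills leave an uncovered gap. With
#' `carryover = FALSE` each fill covers forward from its own date and any
#' surplus still held when the next fill arrives is discarded (a
#' no-stockpiling sensitivity variant).
#'
#' When no truncation is applied and `carryover = TRUE`, total covered days
#' equal total tablets dispensed divided by the daily dose.
#'
#' @param dispensations Tibble with `patient_id`, `dispense_date`, `tablets`.
#' @param dose_per_day Tablets consumed per day (default 1).
#' @param carryover Honour stockpiling of early refills (default `TRUE`).
#' @return A tibble with `patient_id`, `start`, `end` (`Date`; half-open
#'   intervals, disjoint and sorted within patient).
#' @examples
#' d <- tibble::tibble(
#'   patient_id = "A",
#'   dispense_date = as.Date("2022-01-01") + c(0, 25),
#'   tablets = c(30L, 30L)
#' )
#' build_supply_timelines(d) # one interval of 60 days
#' @export
build_supply_timelines <- function(dispensations, dose_per_day = 1,
                                   carryover = TRUE) {
  if (dose_per_day <= 0) abort("`dose_per_day` must be positive.")
  if (nrow(dispensations) == 0) {
    return(tibble(patient_id = character(),
                  start = as.Date(character()),
                  end = as.Date(character())))
  }
  df <- dispensations |>
    transmute(patient_id = .data$patient_id,
              day = as.numeric(.data$dispense_date),
              dur = .data$tablets / dose_per_day) |>
    arrange(.data$patient_id, .data$day)

  # Single-pass vectorised sweep over all patients: rows are sorted by
  # (patient, day); `new` marks each patient's first row and `gid` numbers
  # patients, so group-wise cumsum/cummax reduce to global ones with a
  # per-group offset (1e9 exceeds any day-number magnitude).
  n <- nrow(df)
  day <- df$day
  dur <- df$dur
  new <- !duplicated(df$patient_id)
  gid <- cumsum(new)
  starts_at <- which(new)
  rl <- diff(c(starts_at, n + 1L))
  gcummax <- function(x) cummax(x + gid * 1e9) - gid * 1e9

  if (carryover) {
    # coverage end_i = group-cumsum(dur)_i + max_{k<=i}(day_k - cumsum_{k-1})
    cs <- cumsum(dur)
    cum <- cs - rep(cs[starts_at] - dur[starts_at], rl)
    lag_cum <- c(0, cum[-n])
    lag_cum[new] <- 0
    end <- cum + gcummax(day - lag_cum)
    start <- end - dur
  } else {
    nxt <- c(day[-1], Inf)
    nxt[c(new[-1], TRUE)] <- Inf # last row of each patient
    start <- day
    end <- pmin(day + dur, pmax(nxt, day))
    keep <- end > start # same-day refill supersedes (surplus discarded)
    if (!all(keep)) {
      df <- df[keep, , drop = FALSE]
      n <- nrow(df)
      day <- start[keep]
      start <- day
      end <- end[keep]
      new <- !duplicated(df$patient_id)
      gid <- cumsum(new)
      gcummax <- function(x) cummax(x + gid * 1e9) - gid * 1e9
    }
  }

  # merge touching/overlapping pieces into maximal disjoint intervals;
  # `end` is non-decreasing within patient, so a piece opens a new interval
  # iff it starts after everything covered so far
  prev_end <- c(-Inf, gcummax(end)[-n])
  prev_end[new] <- -Inf
  b <- which(start > prev_end)
  last <- c(b[-1] - 1L, n)
  tibble(
    patient_id = df$patient_id[b],
    start = as.Date(round(start[b]), origin = "1970-01-01"),
    end = as.Date(round(end[last]), origin = "1970-01-01")
  )
}

#' Covered days within an observation window
#'
#' Sums, per patient, the length of the intersection of each coverage
#' interval with the half-open day window `[window_start, window_end)`.
#'
#' @param timelines Output of [build_supply_timelines()].
#' @param window_start,window_end Dates; the window is half-open, so a
#'   window of one calendar day is `[d, d + 1)`.
#' @return A tibble with `patient_id` and `covered_days`. Patients present
#'   in `timelines` but without coverage in the window get 0.
#' @export
coverage_days <- function(timelines, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start >= window_end) {
    abort("`window_start` must precede `window_end`.")
  }
  timelines |>
    mutate(ov = pmax(0, as.numeric(pmin(.data$end, window_end)) -
                        as.numeric(pmax(.data$start, window_start)))) |>
    group_by(.data$patient_id) |>
    summarise(covered_days = sum(.data$ov), .groups = "drop")
}
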