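suppressPackageStartupMessages(library(dplyr))

# -- tiny registry builders ---------------------------------------------------

make_prescriptions <- function(patient_id, issue_date, tablets,
                               atc_code = "C10AA05",
                               prescription_id = NULL) {
  n <- max(length(patient_id), length(issue_date), length(tablets))
  tibble::tibble(
    prescription_id = prescription_id %||% sprintf("R%04d", seq_len(n)),
    patient_id = rep_len(patient_id, n),
    issue_date = rep_len(as.Date(issue_date), n),
    atc_code = rep_len(atc_code, n),
    tablets = as.integer(rep_len(tablets, n))
  )
}

make_dispensations <- function(patient_id, dispense_date, tablets,
                               prescription_id = NULL) {
  n <- max(length(patient_id), length(dispense_date), length(tablets))
  tibble::tibble(
    prescription_id = prescription_id %||% sprintf("R%04d", seq_len(n)),
    patient_id = rep_len(patient_id, n),
    dispense_date = rep_len(as.Date(dispense_date), n),
    tablets = as.integer(rep_len(tablets, n))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random per-patient dispensation histories for property tests
random_dispensations <- function(n_patients, max_events = 10,
                                 origin = as.Date("2022-01-01"),
                                 span_days = 300, max_tablets = 90,
                                 seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_patients), function(i) {
      k <- sample(max_events, 1)
      make_dispensations(
        patient_id = sprintf("P%03d", i),
        dispense_date = origin + sample(0:span_days, k, replace = TRUE),
        tablets = sample(max_tablets, k, replace = TRUE),
        prescription_id = sprintf("R%03d_%02d", i, seq_len(k))
      )
    })
  })
}

# -- independent oracles ------------------------------------------------------

# day-by-day stock simulation: the patient receives tablets on the dispense
# day (before consuming) and swallows one per day while stock lasts
oracle_covered_days <- function(dispensations, from, to) {
  days <- seq(as.Date(from), as.Date(to), by = "day")
  recv <- split(as.numeric(dispensations$tablets),
                as.character(dispensations$dispense_date))
  stock <- 0
  covered <- logical(length(days))
  for (j in seq_along(days)) {
    got <- recv[[as.character(days[j])]]
    if (!is.null(got)) stock <- stock + sum(got)
    if (stock >= 1) {
      stock <- stock - 1
      covered[j] <- TRUE
    }
  }
  sum(covered)
}

# hand product-limit estimator (no ties handling beyond grouping equal times)
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  tibble::tibble(time = ut, survival = out)
}
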