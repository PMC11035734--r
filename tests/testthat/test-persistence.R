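ws22 <- as.Date("2022-01-01")

# dispensations placed relative to the 2022 persistence window start
day <- function(offset) ws22 + offset

test_that("a refill inside the grace period preserves persistence", {
  # exhaustion at day 30; next fill day 55 (gap 25 <= 30): persistent
  # through that gap, then discontinued at the day-85 exhaustion
  d <- make_dispensations("A", day(c(0, 55)), c(30, 30))
  tl <- build_supply_timelines(d)
  out <- detect_discontinuation(tl)
  expect_true(out$discontinued)
  expect_equal(out$duration_days, 85)
})

test_that("a refill just past the grace period is a discontinuation", {
  # exhaustion at day 30; next fill day 61 (gap 31 > 30): event at day 30
  d <- make_dispensations("A", day(c(0, 61)), c(30, 30))
  out <- detect_discontinuation(build_supply_timelines(d))
  expect_true(out$discontinued)
  expect_equal(out$duration_days, 30)
  expect_equal(out$duration_months, 30 / 30.4375)
})

test_that("carry-in supply from before the window start counts", {
  # 90 tablets filled 2021-12-02 cover until day 60 of 2022
  d <- make_dispensations("A", as.Date("2021-12-02"), 90)
  out <- detect_discontinuation(build_supply_timelines(d))
  expect_true(out$discontinued)
  expect_equal(out$duration_days, 60)
})

test_that("patients covered to the window end are censored", {
  d <- make_dispensations("A", day(0), 400)
  out <- detect_discontinuation(build_supply_timelines(d))
  expect_false(out$discontinued)
  expect_equal(out$duration_days, 365)
})

test_that("right-edge gaps follow the configured boundary convention", {
  # exhaustion at day 350, never refilled; the window ends day 364, so the
  # grace period cannot fully elapse inside the data
  d <- make_dispensations("A", day(0), 350)
  tl <- build_supply_timelines(d)
  ev <- detect_discontinuation(tl) # default: counts as discontinuation
  expect_true(ev$discontinued)
  expect_equal(ev$duration_days, 350)
  cn <- detect_discontinuation(tl, boundary = "censor")
  expect_false(cn$discontinued)
  expect_equal(cn$duration_days, 365)
})

test_that("death censors before a gap can qualify", {
  d <- make_dispensations("A", day(0), 100)
  pat <- tibble::tibble(patient_id = "A", death_date = day(80))
  out <- detect_discontinuation(build_supply_timelines(d), patients = pat)
  expect_false(out$discontinued)
  expect_equal(out$duration_days, 81) # through the death day
})

test_that("longer grace periods never shorten persistence", {
  d <- random_dispensations(30, origin = as.Date("2021-11-01"),
                            span_days = 380, seed = 23)
  tl <- build_supply_timelines(d)
  g20 <- detect_discontinuation(tl, grace_days = 20)
  g40 <- detect_discontinuation(tl, grace_days = 40)
  joined <- dplyr::inner_join(g20, g40, by = "patient_id",
                              suffix = c("_20", "_40"))
  expect_true(all(joined$duration_days_40 >= joined$duration_days_20))
})

test_that("Kaplan-Meier matches the hand product-limit on a small cohort", {
  out <- tibble::tibble(
    patient_id = letters[1:3],
    duration_days = c(2, 4, 6) * 30.4375,
    duration_months = c(2, 4, 6),
    discontinued = c(TRUE, FALSE, TRUE)
  )
  km <- kaplan_meier(out)
  expect_equal(km_survival_at(km, 2), 2 / 3)
  expect_equal(km_survival_at(km, 5.9), 2 / 3)
  expect_equal(km_survival_at(km, 6), 0)
  oracle <- oracle_km(out$duration_months, out$discontinued)
  got <- tidy(km)
  expect_equal(got$survival[got$n_event > 0], oracle$survival)
})

test_that("with zero censoring Kaplan-Meier is the empirical survival", {
  t <- withr::with_seed(5, rexp(300, 0.1))
  out <- tibble::tibble(patient_id = as.character(seq_along(t)),
                        duration_days = t * 30.4375, duration_months = t,
                        discontinued = TRUE)
  km <- kaplan_meier(out)
  for (q in c(2, 5, 10, 20)) {
    expect_equal(km_survival_at(km, q), mean(t > q))
  }
})

test_that("all-censored input keeps survival at 1", {
  out <- tibble::tibble(patient_id = c("a", "b"), duration_days = c(365, 365),
                        duration_months = c(12, 12),
                        discontinued = c(FALSE, FALSE))
  km <- kaplan_meier(out)
  expect_equal(km_survival_at(km, 12), 1)
  s <- summarize_persistence(out)
  expect_equal(s$persistence_at, 1)
  expect_equal(s$mean_months, 12)
})

test_that("KM on censored exponential durations tracks the analytic curve", {
  lambda <- 0.0764
  t <- withr::with_seed(17, rexp(1000, lambda))
  out <- tibble::tibble(
    patient_id = as.character(seq_along(t)),
    duration_days = pmin(t, 12) * 30.4375,
    duration_months = pmin(t, 12),
    discontinued = t <= 12
  )
  km <- kaplan_meier(out)
  grid <- seq(0.5, 11.5, by = 0.5)
  sup_diff <- max(abs(km_survival_at(km, grid) - exp(-lambda * grid)))
  expect_lt(sup_diff, 0.05)
})

test_that("baseline cohort keeps only patients with supply on hand", {
  d <- dplyr::bind_rows(
    make_dispensations("active", as.Date("2021-12-15"), 60,
                       prescription_id = "R1"),
    make_dispensations("lapsed", as.Date("2021-08-01"), 30,
                       prescription_id = "R2"),
    make_dispensations("new", as.Date("2022-02-01"), 30,
                       prescription_id = "R3")
  )
  expect_equal(persistence_cohort(d), "active")
})

test_that("persistence sampling is reproducible and exhaustive at n = N", {
  ids <- sprintf("P%03d", 1:50)
  expect_setequal(sample_persistence_cohort(ids, 50, seed = 1), ids)
  s1 <- sample_persistence_cohort(ids, 10, seed = 9)
  s2 <- sample_persistence_cohort(ids, 10, seed = 9)
  expect_identical(s1, s2)
  expect_length(unique(s1), 10)
  expect_warning(sample_persistence_cohort(ids, 60, seed = 1), "eligible")
})

test_that("a sampled subcohort reproduces the full-cohort KM at 12 months", {
  p <- cohort_params(n_patients = 6000)
  sim <- simulate_cohort(p, seed = 41)
  tl <- build_supply_timelines(sim$dispensations)
  elig <- persistence_cohort(sim$dispensations)
  full <- detect_discontinuation(tl, ids = elig, patients = sim$patients)
  s_full <- summarize_persistence(full)$persistence_at
  sub <- sample_persistence_cohort(elig, 500, seed = 8)
  s_sub <- summarize_persistence(
    detect_discontinuation(tl, ids = sub, patients = sim$patients)
  )$persistence_at
  se <- sqrt(s_full * (1 - s_full) / 500)
  expect_lt(abs(s_sub - s_full), 3 * se)
})
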