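write_registry_fixture <- function(dir, rx, disp, pat = NULL) {
  dir.create(dir, showWarnings = FALSE)
  readr::write_csv(rx, file.path(dir, "prescriptions.csv"))
  readr::write_csv(disp, file.path(dir, "dispensations.csv"))
  if (!is.null(pat)) readr::write_csv(pat, file.path(dir, "patients.csv"))
  dir
}

test_that("reader parses well-formed rows identically and types dates", {
  d <- withr::local_tempdir()
  rx <- make_prescriptions("A", c("2020-02-01", "2020-03-01", "2020-04-01"),
                           c(30, 60, 28))
  disp <- make_dispensations("A", c("2020-02-03", "2020-03-02"), c(30, 60),
                             prescription_id = c("R0001", "R0002"))
  write_registry_fixture(d, rx, disp)
  reg <- read_registry(file.path(d, "prescriptions.csv"),
                       file.path(d, "dispensations.csv"), quiet = TRUE)
  expect_equal(nrow(reg$prescriptions), 3)
  expect_s3_class(reg$prescriptions$issue_date, "Date")
  expect_equal(as.data.frame(reg$prescriptions), as.data.frame(rx),
               ignore_attr = TRUE)
  expect_equal(nrow(reader_log(reg$prescriptions)), 0)
})

test_that("invalid rows are rejected with counted diagnostics", {
  d <- withr::local_tempdir()
  rx <- make_prescriptions("A", c("2020-02-01", "2020-03-01", "2020-04-01"),
                           c(30, -5, 28))
  rx$issue_date <- as.character(rx$issue_date)
  rx$issue_date[3] <- "31/04/2020"
  disp <- make_dispensations("A", "2020-02-03", 30)
  write_registry_fixture(d, rx, disp)
  expect_message(
    reg <- read_registry(file.path(d, "prescriptions.csv"),
                         file.path(d, "dispensations.csv")),
    "dropped"
  )
  expect_equal(nrow(reg$prescriptions), 1)
  log <- reader_log(reg$prescriptions)
  expect_equal(sum(log$n[log$issue == "invalid_tablets"]), 1)
  expect_equal(sum(log$n[log$issue == "malformed_date"]), 1)
})

test_that("exact duplicate rows are dropped once and logged", {
  d <- withr::local_tempdir()
  rx <- make_prescriptions("A", "2020-02-01", 30)
  rx <- rbind(rx, rx)
  disp <- make_dispensations("A", "2020-02-03", 30)
  write_registry_fixture(d, rx, disp)
  reg <- read_registry(file.path(d, "prescriptions.csv"),
                       file.path(d, "dispensations.csv"), quiet = TRUE)
  expect_equal(nrow(reg$prescriptions), 1)
  expect_equal(reader_log(reg$prescriptions)$n[
    reader_log(reg$prescriptions)$issue == "exact_duplicate"], 1)
})

test_that("unknown columns are ignored with a warning", {
  d <- withr::local_tempdir()
  rx <- make_prescriptions("A", "2020-02-01", 30)
  rx$payer_code <- "NFZ"
  disp <- make_dispensations("A", "2020-02-03", 30)
  write_registry_fixture(d, rx, disp)
  expect_warning(
    reg <- read_registry(file.path(d, "prescriptions.csv"),
                         file.path(d, "dispensations.csv"), quiet = TRUE),
    "payer_code"
  )
  expect_false("payer_code" %in% names(reg$prescriptions))
})

test_that("write_registry / read_registry round-trips field-for-field", {
  sim <- simulate_cohort(cohort_params(n_patients = 40), seed = 5)
  d <- withr::local_tempdir()
  write_registry(sim, d)
  reg <- read_registry(file.path(d, "prescriptions.csv"),
                       file.path(d, "dispensations.csv"),
                       file.path(d, "patients.csv"), quiet = TRUE)
  expect_equal(as.data.frame(reg$prescriptions),
               as.data.frame(sim$prescriptions), ignore_attr = TRUE)
  expect_equal(as.data.frame(reg$dispensations),
               as.data.frame(sim$dispensations), ignore_attr = TRUE)
  expect_equal(as.data.frame(reg$patients), as.data.frame(sim$patients),
               ignore_attr = TRUE)
})

test_that("statin filter keeps C10AA and listed C10BA codes only", {
  ev <- tibble::tibble(atc_code = c("C10AA05", "C10BA02", "C10BX03"))
  expect_equal(filter_statin_atc(ev)$atc_code, c("C10AA05", "C10BA02"))
  # other lipid-lowering classes: fibrates, ezetimibe
  ev2 <- tibble::tibble(atc_code = c("C10AB05", "C10AX09"))
  expect_equal(nrow(filter_statin_atc(ev2)), 0)
  # C10BA10 is not part of the enumerated combination set
  expect_equal(nrow(filter_statin_atc(tibble::tibble(atc_code = "C10BA10"))), 0)
  expect_equal(filter_statin_atc(
    tibble::tibble(atc_code = c("C10BA01", "C10BA09", "C10BA11", "C10BA12"))
  )$atc_code, c("C10BA01", "C10BA09", "C10BA11", "C10BA12"))
})

test_that("statin filter is idempotent, subsetting, and warns on bad codes", {
  ev <- tibble::tibble(atc_code = c("C10AA01", "C10", "", "C09AA05"))
  expect_warning(out <- filter_statin_atc(ev), "excluded")
  expect_equal(out$atc_code, "C10AA01")
  expect_equal(suppressWarnings(filter_statin_atc(out)), out)
  expect_true(all(out$atc_code %in% ev$atc_code))
})

test_that("inclusion requires a dispensation inside the window", {
  w <- study_window()
  disp <- make_dispensations(c("A", "C"), c("2020-06-01", "2023-01-02"),
                             c(30, 30))
  # B is prescribed only; C dispensed after the window end
  expect_equal(include_patients(disp, w), "A")
  expect_equal(include_patients(disp[0, ], w), character())
})

test_that("dispensation linkage enforces date and quantity invariants", {
  rx <- make_prescriptions("A", "2020-02-01", 30,
                           prescription_id = c("R0001"))
  disp <- make_dispensations(
    "A", c("2020-02-03", "2020-01-20", "2020-02-05", "2020-02-06"),
    c(30, 30, 45, 20),
    prescription_id = c("R0001", "R0001", "R0001", "R9999")
  )
  out <- suppressMessages(link_dispensations(disp, rx))
  expect_equal(nrow(out), 1)
  expect_equal(out$dispense_date, as.Date("2020-02-03"))
  log <- reader_log(out)
  expect_setequal(log$issue, c("orphan_prescription",
                               "dispensed_before_issue",
                               "dispensed_over_prescribed"))
})
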