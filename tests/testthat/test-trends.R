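test_that("weekly aggregation places each event in its own ISO week", {
  rx <- make_prescriptions("A", "2020-01-08", 30)
  disp <- make_dispensations("A", "2020-01-10", 30)
  w <- aggregate_weekly(rx, disp)
  expect_equal(nrow(w), 156)
  wk <- w[w$iso_year == 2020 & w$iso_week == 2, ]
  expect_equal(wk$prescribed_tablets, 30)
  expect_equal(wk$dispensed_tablets, 30)
  expect_equal(sum(w$prescribed_tablets), 30)
})

test_that("an empty registry yields an all-zero 156-week series", {
  w <- aggregate_weekly(make_prescriptions(character(), character(), integer()),
                        make_dispensations(character(), character(), integer()))
  expect_equal(nrow(w), 156)
  expect_true(all(w$prescribed_tablets == 0) && all(w$dispensed_tablets == 0))
})

test_that("aggregation matches a naive per-event tally and conserves totals", {
  sim <- simulate_cohort(cohort_params(n_patients = 120), seed = 14)
  w <- aggregate_weekly(sim$prescriptions, sim$dispensations)
  # brute force: loop over events, accumulate per (iso_year, iso_week)
  tally <- new.env()
  for (i in seq_len(nrow(sim$prescriptions))) {
    k <- sprintf("%d-%02d",
                 lubridate::isoyear(sim$prescriptions$issue_date[i]),
                 lubridate::isoweek(sim$prescriptions$issue_date[i]))
    tally[[k]] <- (tally[[k]] %||% 0) + sim$prescriptions$tablets[i]
  }
  got <- w$prescribed_tablets
  names(got) <- sprintf("%d-%02d", w$iso_year, w$iso_week)
  for (k in ls(tally)) expect_equal(unname(got[k]), tally[[k]], info = k)
  expect_equal(sum(w$prescribed_tablets), sum(sim$prescriptions$tablets))
  expect_equal(sum(w$dispensed_tablets), sum(sim$dispensations$tablets))
})

test_that("events outside the window are excluded and logged", {
  rx <- make_prescriptions("A", c("2019-12-30", "2020-06-01"), 30)
  w <- aggregate_weekly(rx, make_dispensations(character(), character(),
                                               integer()))
  expect_equal(sum(w$prescribed_tablets), 30)
  log <- reader_log(w)
  expect_equal(log$n[log$table == "prescriptions"], 1)
})

test_that("weekly percentage dispensed is the same-week ratio", {
  w <- aggregate_weekly(make_prescriptions("A", "2020-06-01", 1000),
                        make_dispensations("A", "2020-06-03", 860))
  p <- percent_dispensed(w)
  expect_equal(p$pct_dispensed[p$iso_year == 2020 & p$iso_week == 23], 86)
  expect_true(all(is.na(p$pct_dispensed[p$prescribed_tablets == 0])))
  # scale invariance: multiplying tablet counts leaves percentages unchanged
  w2 <- dplyr::mutate(w, prescribed_tablets = prescribed_tablets * 7,
                      dispensed_tablets = dispensed_tablets * 7)
  expect_equal(percent_dispensed(w2)$pct_dispensed, p$pct_dispensed)
})

test_that("the overall fill percentage reproduces the printed rounding", {
  expect_equal(round(overall_fill_percentage(4010716658, 4681614262)), 86)
  expect_equal(overall_fill_percentage(860, 1000), 86)
  expect_error(overall_fill_percentage(1, 0), "positive")
})

test_that("per-capita rates normalise by the week's ISO-year population", {
  keys <- iso_week_keys(study_window())
  w <- keys |>
    dplyr::mutate(prescribed_tablets = 38089000, dispensed_tablets = 0)
  out <- per_capita_rate(w)
  expect_equal(out$prescribed_tablets_per_1000[out$iso_year == 2020][1], 1000)
  # constant series jumps across the year boundary by the population ratio
  r21 <- out$prescribed_tablets_per_1000[out$iso_year == 2021][1]
  expect_equal(r21, 1000 * 38089 / 37908)
  expect_error(per_capita_rate(w, tibble::tibble(year = 2020,
                                                 population = 1)),
               "No population")
})

test_that("the OLS trend recovers exact linear series to machine precision", {
  keys <- iso_week_keys(study_window())
  v <- seq(84.9, 87.4, length.out = 156)
  fit <- fit_linear_trend(dplyr::mutate(keys, v = v), v)
  expect_equal(fit$slope, 2.5 / 155, tolerance = 1e-12)
  expect_equal(round(fit$slope, 3), 0.016)
  expect_equal(fit$fitted_first, 84.9)
  expect_equal(fit$fitted_last, 87.4)
  expect_lt(fit$p_value, 0.05)
  flat <- fit_linear_trend(dplyr::mutate(keys, v = 5), v)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
})

test_that("trend slopes on noisy linear data sit within 3 SE of truth", {
  keys <- iso_week_keys(study_window())
  slope <- 0.02
  v <- 80 + slope * keys$week_index + withr::with_seed(11, rnorm(156, 0, 1))
  fit <- fit_linear_trend(dplyr::mutate(keys, v = v), v)
  se <- tidy(fit)$std_error[2]
  expect_lt(abs(fit$slope - slope), 3 * se)
})

test_that("endpoint percent changes reproduce printed one-decimal values", {
  expect_equal(percent_change_endpoints(27418954, 32601689), 18.9)
  expect_equal(percent_change_endpoints(23133631, 28285831), 22.3)
  expect_equal(percent_change_endpoints(5, 5), 0)
  expect_error(percent_change_endpoints(0, 5), "positive")
})

test_that("quarter aggregation pools ISO weeks 1-13/14-26/27-39/40+", {
  keys <- iso_week_keys(study_window())
  v <- dplyr::case_when(keys$iso_week <= 13 ~ 82,
                        keys$iso_week <= 26 ~ 85,
                        keys$iso_week <= 39 ~ 87, TRUE ~ 87)
  q <- aggregate_quarters(dplyr::mutate(keys, v = v), v)
  expect_equal(q$quarter, 1:4)
  expect_equal(q$mean, c(82, 85, 87, 87))
  expect_equal(q$sd[1], 0)
  cmp <- compare_quarters(dplyr::mutate(keys, v = v), v)
  q13 <- cmp[cmp$quarter_a == 1 & cmp$quarter_b == 3, ]
  expect_equal(q13$diff, 5)
  expect_lt(q13$p_value, 0.05)
  # constant series: all quarters equal, nothing significant
  cst <- compare_quarters(dplyr::mutate(keys, v = 86), v)
  expect_true(all(cst$diff == 0))
  expect_true(all(cst$p_value > 0.05))
})

test_that("a seasonal first-quarter trough is detected across years", {
  keys <- iso_week_keys(study_window())
  v <- ifelse(keys$iso_week <= 13, 82, 87) +
    withr::with_seed(3, rnorm(156, 0, 2))
  q <- aggregate_quarters(dplyr::mutate(keys, v = v), v)
  expect_lt(q$mean[q$quarter == 1], q$mean[q$quarter == 3])
  cmp <- compare_quarters(dplyr::mutate(keys, v = v), v)
  expect_lt(cmp$p_value[cmp$quarter_a == 1 & cmp$quarter_b == 3], 0.05)
})

test_that("between-year comparison reproduces the hand-ranked H statistic", {
  s <- tibble::tibble(iso_year = rep(2020:2022, each = 3),
                      v = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  out <- compare_years(s, v)
  expect_equal(out$statistic, 7.2)
  expect_lt(out$p_value, 0.05)
})

test_that("identical yearly distributions give H = 0 and p = 1", {
  s <- tibble::tibble(iso_year = rep(2020:2022, each = 3),
                      v = rep(c(1, 2, 3), 3))
  out <- compare_years(s, v)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  cst <- compare_years(tibble::tibble(iso_year = rep(2020:2022, each = 3),
                                      v = 86), v)
  expect_equal(cst$statistic, 0)
  expect_equal(cst$p_value, 1)
})

test_that("equal-mean yearly series rarely reject under the null", {
  keys <- iso_week_keys(study_window())
  rejections <- withr::with_seed(29, {
    vapply(seq_len(200), function(i) {
      s <- dplyr::mutate(keys, v = rnorm(156, 86, 4))
      compare_years(s, v)$p_value < 0.05
    }, logical(1))
  })
  expect_gte(mean(!rejections), 0.90)
})

test_that("normality gate reports which location summary applies", {
  keys <- iso_week_keys(study_window())
  gaussian <- compare_years(dplyr::mutate(
    keys, v = withr::with_seed(2, rnorm(156, 86, 2))), v)
  expect_true(gaussian$normal)
  skewed <- compare_years(dplyr::mutate(
    keys, v = withr::with_seed(2, rexp(156, 1))), v)
  expect_false(skewed$normal)
  expect_equal(nrow(tidy(skewed)), 3)
})
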