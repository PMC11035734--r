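# rxflow

Claims-registry analytics for chronic cardiovascular pharmacotherapy:
tablet-standardised utilisation series, Medication Possession Ratio (MPR)
adherence, grace-period persistence with Kaplan-Meier estimation, and
lockdown/COVID-19 context analysis — built for national e-prescription
data on statins, together with a synthetic registry generator so the whole
pipeline is testable without access to confidential payer data.

## Who it is for

Pharmacoepidemiologists and drug-utilisation researchers working with
prescription/dispensation event tables (one row per issued or filled
e-prescription line). The package takes plain CSV registries in, returns
tibbles out, and its functions chain with the pipe.

## The measurements at its core

All quantities are in tablets, with every retained statin product
interchangeable at 1 tablet/day; pack equivalents use a 30-tablet
standard pack.

**Supply timelines.** Dispensations become disjoint half-open coverage
intervals with refill carryover: a fill of $q$ tablets on day $d$ adds
$q$ covered days starting at $\max(d, \text{current exhaustion})$, so
early refills stockpile and late refills leave gaps.

**Adherence.** For patient $i$ observed from first dispensation $t_{0i}$
to study end (or death),

$$\mathrm{MPR}_i = \min\!\left(1,\ \frac{\text{covered days in window}_i}{\text{window days}_i}\right),$$

with adherence classified at MPR ≥ 0.80 (and 0.90 as a stricter
threshold).

**Persistence.** Discontinuation occurs at the first supply-exhaustion
date not followed by renewed coverage within a 30-day grace period;
durations (months of 30.4375 days) are censored at death or window end
and summarised by the Kaplan–Meier product-limit estimator
$\hat S(t) = \prod_{t_j \le t} (1 - d_j / n_j)$.

**Utilisation and context.** ISO-week aggregation (156 weeks for the
default 2020-01-08 – 2022-12-31 window), weekly %-dispensed, per-1000
rates, OLS trends, quarterly and between-year rank tests
(Kruskal–Wallis with a Shapiro–Wilk gate), Spearman correlation with
weekly COVID-19 counts, and lockdown contrasts — both the raw two-group
comparison and an interrupted-time-series estimator that adjusts for
secular trend and week-of-year seasonality.

The methods vignette (`vignettes/statin-claims-pipeline.Rmd`) documents
every convention and the generator's design.

## Worked example

```r
library(rxflow)
library(dplyr)

# a synthetic national registry: 10,000 statin users, 2020-2022
sim <- simulate_cohort(cohort_params(), study_window(), seed = 1)

weekly <- aggregate_weekly(sim$prescriptions, sim$dispensations) |>
  percent_dispensed() |>
  per_capita_rate() |>
  lockdown_flags()

summarise(weekly,
  prescribed = sum(prescribed_tablets), dispensed = sum(dispensed_tablets),
  fill_pct = overall_fill_percentage(dispensed, prescribed))
#> # A tibble: 1 × 3
#>   prescribed dispensed fill_pct
#>        <dbl>     <dbl>    <dbl>
#> 1    3462022   2977940     86.0

tablets_to_packs(sum(weekly$dispensed_tablets))
#> [1] 99265

# adherence
adh <- adherence_records(sim$dispensations, sim$patients)
cohort_adherence(adh)
#> # A tibble: 2 × 4
#>   threshold     n n_adherent pct_adherent
#>       <dbl> <int>      <int>        <dbl>
#> 1       0.8  9958       3690         37.1
#> 2       0.9  9958       3311         33.2

# persistence over 2022 on users with supply on hand at baseline
tl <- build_supply_timelines(sim$dispensations)
eligible <- persistence_cohort(sim$dispensations)
outcomes <- detect_discontinuation(tl, ids = eligible, patients = sim$patients)
kaplan_meier(outcomes)
#> <rxflow_km> Kaplan-Meier persistence curve
#>   n = 2701, events = 1621
#>   S(12 months) = 0.388; mean observed duration = 7.74 +/- 4.29 months

# lockdown effect on weekly prescribing, net of trend and seasonality
estimate_lockdown_deficit(weekly, prescribed_tablets)
#> # A tibble: 1 × 4
#>   percent_deficit multiplier p_value     n
#>             <dbl>      <dbl>   <dbl> <int>
#> 1            6.45      0.936 0.00838   156
```

Reading the output: 86.0% of issued tablets were filled (the generator's
primary non-adherence default is 14%); 37% of patients held medication on
at least 80% of their observed days; of patients on therapy on
1 January 2022, 38.8% were still refilling without a >30-day gap twelve
months later (the generator's stopping hazard, 0.0764/month, has
closed-form 12-month survival 0.40); and lockdown weeks carried 6.5%
fewer prescribed tablets than comparable open weeks (configured
multiplier 0.932, i.e. a 6.8% deficit).

`plot_weekly_series()`, `plot_percent_dispensed()`, `plot_covid_overlay()`
and `autoplot()` on the KM object draw the standard figures;
`tidy()`/`glance()` return broom-style summaries. `run_pipeline()` runs
ingest → filter → weekly → adherence → persistence → COVID context
end-to-end from a `pipeline_config()` (or YAML file) and writes
`weekly_series.csv`, `adherence.csv`, `persistence.csv`, `km_curve.csv`,
`covid_report.json`, `summary.json` and a run log;
`inst/cli/rxflow.R` exposes `simulate` / `analyze` / `report`
subcommands over the same functions.

## Registry schema

```
prescriptions.csv: prescription_id,patient_id,issue_date,atc_code,tablets
dispensations.csv: prescription_id,patient_id,dispense_date,tablets
patients.csv:      patient_id,sex,birth_year,death_date   (death_date optional)
covid_weekly.csv:  country,year_week,indicator,weekly_count   (ECDC dialect)
```

Dates are ISO-8601; dispensations may partially fill a prescription and a
prescription may be filled in several events. The readers validate rows,
drop exact duplicates, and attach per-table diagnostics
(`reader_log()`).

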