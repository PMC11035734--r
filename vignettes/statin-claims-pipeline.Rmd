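---
title: "Methods: tablet-standardised claims analysis of statin adherence and persistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tablet-standardised claims analysis of statin adherence and persistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rxflow analyses national e-prescription registries of chronic
cardiovascular medication, with statin therapy as the worked case. This
vignette is the package's account of its methods: the measurement
conventions, the statistical procedures, the synthetic registry generator
that stands in for confidential payer data, and the design choices made
where the underlying conventions are genuinely open.

## The measurement problem

An e-prescription registry records two event streams per patient:
prescriptions issued (date, ATC code, tablet quantity) and dispensations
(date, tablet quantity, linked prescription). From these the package
derives three families of results:

1. **Utilisation series** — weekly tablet totals prescribed and dispensed,
   the weekly percentage dispensed, per-1000-inhabitant rates, and
   standard-pack equivalents.
2. **Adherence** — the Medication Possession Ratio (MPR) per patient, and
   the cohort percentage adherent at possession thresholds.
3. **Persistence** — time to therapy discontinuation under a grace-period
   rule, summarised by the Kaplan-Meier product-limit estimator.

All quantities are in tablets. Statin products are treated as
interchangeable at one tablet per day regardless of compound and strength:
generic substitution is routine for this class, packs come in 28/30
tablets and multiples, and standardising on the tablet avoids pack-size
artefacts. Pack equivalents use a 30-tablet standard pack with half-away-
from-zero rounding.

The inclusion filter keeps plain statins (ATC `C10AA*`) and fixed
combinations of statins with other lipid-modifying agents (`C10BA01`-`09`,
`C10BA11`, `C10BA12`). Combinations with non-lipid drugs (`C10BX`) and
other lipid-lowering classes (ezetimibe, fibrates) are excluded. A patient
enters the cohort with their first statin dispensation inside the study
window; prescriptions never filled do not qualify a patient.

## Supply timelines

`build_supply_timelines()` converts dispensations into disjoint half-open
coverage intervals `[start, end)` at day resolution; a fill on day `d`
covers `d` itself. The default honours **carryover**: supply collected
before the previous fill has run out is stockpiled, so each fill adds
`tablets / dose_per_day` covered days starting at the later of its date
and the current exhaustion date. Under carryover and without truncation,
covered days equal tablets dispensed exactly — an invariant the test suite
checks against an independent day-by-day stock simulation. A
`carryover = FALSE` variant discards surplus at each refill for
sensitivity analyses.

## Adherence (MPR)

For each patient the observation window runs from the first statin
dispensation to the study end, or death if earlier, both ends inclusive —
statin therapy is intended as lifelong, so the "intended treatment period"
is the remainder of observation. MPR is covered days divided by window
days, **capped at 1**: stockpiled oversupply does not count as
extra adherence. The capped MPR counts distinct covered days inside the
window (the PDC-style reading); an uncapped diagnostic relating all supply
received to the window is retained per patient. Threshold classification
is inclusive (`mpr >= 0.80` is adherent, consistent with "below 0.80"
defining non-adherence), and the 0.90 threshold is reported alongside.
By construction the percentage adherent at 0.90 can never exceed the
percentage at 0.80.

## Persistence

Non-persistence is a failure to renew supply within a **30-day grace
period** after the previous supply ran out. The discontinuation is
timestamped at the exhaustion date, not at grace expiry: the clinically
relevant moment is when the patient stopped holding medication. Durations
convert to months at 365.25/12 = 30.4375 days.

The persistence analysis follows the registry convention of a fixed
analysis year (default 2022) on established users, with supply
**carried in** from earlier dispensations:

* **Baseline eligibility.** "Users before the baseline" is operationalised
  as patients whose stockpile covers the baseline day itself. Including
  ex-users whose therapy lapsed long before baseline would put a mass of
  zero-duration events at the origin and make the curve start below 1;
  anchoring everyone in the on-therapy state makes `S(0) = 1` and gives
  the curve its usual interpretation.
* **Right-edge convention.** A patient whose supply runs out near the end
  of observation and who never refills within the data is counted as
  discontinued at exhaustion (`boundary = "event"`), even when the full
  grace period does not fit before the horizon. The strict alternative
  (`boundary = "censor"`) leaves the final `grace_days` of the window
  structurally event-free, which flattens the curve over the last month
  and biases the 12-month estimate upward by roughly `exp(lambda/12)`;
  it remains available as a flag. Neither convention can distinguish a
  true stop from a refill that falls just beyond the horizon — an
  identifiability limit of any fixed-window claims analysis.
* **Censoring.** Death and the window end censor; a patient who dies
  during a not-yet-qualifying gap is censored at death.
* Restarters after a qualifying gap are non-persistent from the first
  gap; re-initiation is not analysed.

The survival curve itself is the product-limit estimator via
`survival::survfit()`; the test suite checks it against a hand-written
product-limit oracle and, with zero censoring, against the empirical
survival function. The reported "mean period of continuous therapy" is
the arithmetic mean of observed durations over all sampled patients,
censored durations included window-truncated; with substantial censoring
it understates the true mean time to discontinuation, which is why the
Kaplan-Meier landmark (persistence at 12 months) is the primary summary.

## Weekly series and trends

Weeks are ISO-8601; the default window (2020-01-08 to 2022-12-31)
comprises 156 weeks, with 2020 contributing weeks 2-53 and 2021/2022
weeks 1-52. Each event counts in the week of its own date. The weekly
percentage dispensed is the same-week ratio; the overall fill percentage
`100 * total dispensed / total prescribed` is the aggregate share of
issued tablets that was ever filled — the two differ conceptually and the
package exposes both. Per-1000 rates divide by the week's ISO-year
population in thousands.

Trends are ordinary least squares on the week index; endpoint percent
changes are computed from fitted endpoint values (raw-endpoint use is a
caller choice). Quarters map ISO weeks 1-13, 14-26, 27-39 and 40-end to
Q1-Q4 and pool weekly values across years; pairwise quarter contrasts use
Mann-Whitney tests. Between-year comparisons use Kruskal-Wallis, preceded
by a per-year Shapiro-Wilk check that decides whether means or medians
are the appropriate location summary to report. Degenerate inputs
(constant series) return `H = 0`, `p = 1` rather than erroring. No
multiple-testing correction is applied anywhere, and outputs say so.

## Lockdowns and COVID-19 context

Lockdown periods are configured as inclusive ISO-week ranges — the
default is weeks 12-22 and 46-52 of 2020 plus weeks 12-16 of 2021,
23 weeks in total. Configuring by week range rather than by calendar date
is deliberate: published week ranges and calendar dates for the same
lockdown can disagree by a week under ISO numbering, and the ranges are
taken as authoritative.

Correlations between weekly COVID-19 counts and statin series default to
Spearman (weekly epidemic counts are heavy-tailed; Pearson by flag), with
two-sided p-values. The lockdown contrast comes in two forms:

* `compare_lockdown()` — the descriptive two-group comparison of raw
  weekly values (group means, relative deficit, Mann-Whitney test).
* `estimate_lockdown_deficit()` — an interrupted-time-series-style
  regression of the log weekly value on a quadratic time trend,
  week-of-year fixed effects (week 53 pooled with 52) and the lockdown
  flag, reporting `100 * (1 - exp(beta))`. On a growing cohort the raw
  contrast confounds the lockdown effect with secular growth and with the
  year-end trough that happens to fall inside the 2020 lockdown weeks;
  the adjusted estimator recovers a configured multiplicative lockdown
  effect regardless, and is what the parameter-recovery suite uses.

Matched-week comparisons pair each lockdown week with the same-numbered
week of a lockdown-free reference year (default 2022) under a paired rank
test; week 53 of 2020 has no counterpart and is excluded with a warning.

## The synthetic registry generator

No public instance of the source data exists, so the generator is a
first-class module: every downstream stage is developed and tested
against registries whose ground truth is known. It emulates the
statistical structure that the analysis relies on:

* **Cohort composition.** A configurable fraction of patients
  (default 0.25) are established users when the window opens; the rest
  initiate during the window with intensity proportional to the weekly
  multipliers (including the secular trend). Established users enter at
  the stationary forward-recurrence of their refill cycle — a uniform
  position inside a length-biased cycle — so the aggregate weekly refill
  rate is flat from day one rather than showing cohort-wide echo waves.
* **Refill behaviour.** Refills are anchored to supply exhaustion: the
  next prescription is issued a gamma-distributed lead (default mean
  10 days) before the current stock runs out, and is filled after a short
  geometric delay (mean 2 days). An independent fixed gap between
  prescriptions is not realistic for maintenance therapy and would
  manufacture 30-day gaps among fully persistent patients; anchoring to
  exhaustion reproduces the near-contiguous coverage with occasional
  small gaps seen in maintenance-therapy claims.
* **Primary non-adherence.** Each prescription independently expires
  unfilled with probability 0.14, so the expected fill fraction is 86%.
  An expired prescription is replaced after a tight renewal gap
  (gamma, mean 7 days, shape 16) — e-prescription renewal is quick — so
  isolated failures to fill produce days-long, not month-long, gaps.
* **Stopping.** Therapy ends through per-refill decisions whose hazard
  accrues over supply-exhaustion intervals (default 0.0764 per month,
  the value whose closed-form 12-month survival is 0.40). Because the
  decision is taken at the refill that would extend supply, the
  claims-visible final exhaustion *is* the stopping time; a continuous
  latent stop time would leave nearly a month of already-dispensed
  residual supply between the decision and its claims signature and bias
  measured persistence upward by several points.
* **Calendar effects.** Seasonal multipliers (year-end trough 0.75 in
  weeks 51-53, new-year rebound 1.15 in weeks 1-2) and the lockdown
  multiplier (0.932 on prescribing) stretch refill timing locally through
  an operational-time warp: weekly event intensity is proportional to the
  configured multiplier while every episode self-corrects afterwards as
  patients catch up. The secular trend (+18.9% compounded over the 155
  week-on-week steps of the window) acts on initiation intensity only:
  growth comes from cohort turnover, because warping established users'
  cadence by a cumulative trend would have them accumulate months of
  surplus stock. The dispensing-side lockdown multiplier (0.941) enters
  as a lockdown-time increase in fill probability, so the dispensed
  deficit is smaller than the prescribing deficit and the percentage
  dispensed is slightly higher inside lockdowns.
* **Demographics.** Sex (55.4% F / 44.4% M / 0.2% missing), birth years
  around 1955, and exponential mortality at 3.3%/year.
* **COVID-19 series.** Weekly cases are a sum of Gaussian waves with
  negative-binomial noise; deaths are a lagged case-fatality image
  (default 2%, 2-week lag). The shapes are phenomenological — there is no
  transmission model — which is sufficient for exercising correlation and
  alignment code.

Everything is reproducible from an explicit seed; no global random state
is used.

### What the generator does not emulate

Partial fills (the schema allows them; the generator always fills in
full), molecule switching and strength changes, covariate structure in
adherence (age/sex effects), co-payment and reimbursement effects,
regional heterogeneity, and any mechanistic coupling between the COVID
series and prescribing. Passing parameter-recovery tests therefore shows
that the pipeline measures what the generator encodes — fill fractions,
stopping hazards, calendar effects — not that real registries satisfy
these simplifications.

## Numerical conventions

* Pack equivalents round half away from zero (printed national pack
  counts reproduce exactly under this rule; banker's rounding would not).
* Day-resolution arithmetic throughout; intervals are half-open; a
  one-day window is `[d, d + 1)`.
* Month = 30.4375 days.
* Rank tests on fully degenerate (constant) input return `p = 1`;
  Spearman p-values use the asymptotic approximation (`exact = FALSE`),
  as ties are routine in count data.
* Week 53 pools with week 52 in week-of-year adjustments.
* The KM landmark at 12 months evaluates the step function at the last
  observed time not exceeding 12.

## Problem sizes

The test suite and the acceptance script run the recovery analyses on
10,000-patient registries — large enough that binomial and product-limit
Monte-Carlo error (about 1 percentage point on the 12-month persistence,
about 1 point on the lockdown deficit per replicate) sits well inside the
stated recovery tolerances — and average stochastic recoveries over eight
replicate registries. Unit tests use cohorts of 40-6,000 patients chosen
per property.

## Known limitations

* The right-edge identifiability limit described above: within the final
  grace period, stopping and refilling-after-horizon are
  indistinguishable; the two boundary conventions bracket the truth.
* The mean-of-observed-durations summary mixes events and censored
  follow-up; it is reported for comparability with registry conventions,
  not as an estimate of the mean time to discontinuation.
* Weekly percentage dispensed compares same-week flows; under strong
  within-week growth it is not the probability that an issued
  prescription is ever filled (the aggregate fill percentage and the
  generator's fill probability are the cleaner pair).
* The lockdown regression assumes a multiplicative, synchronous effect
  across all lockdown weeks; dynamic (lagged or transfer-function)
  responses are out of scope.
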