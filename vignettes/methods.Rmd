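---
title: "Methods: new-user cohort drug-safety analysis with time-dependent exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: new-user cohort drug-safety analysis with time-dependent exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tzdsafety)
library(data.table)
```

## The problem

Comparative safety studies of antidiabetic drugs in routine primary-care
records face two structural hazards. First, *confounding by indication*:
in type-2 diabetes, drug choice is driven by disease severity (metformin
first, insulin last), so naïve contrasts between drug classes largely
measure the underlying disease. Second, *immortal time bias*: if
person-time before a patient's first prescription of a drug is counted as
exposed to that drug, the exposed group inherits guaranteed survival up
to that prescription.

`tzdsafety` implements the study design that addresses both: inception
(new-user) cohorts per drug class, time-dependent classification of every
day of follow-up into current / recent / past use per class,
active-comparator censoring, and — crucially — a *negative-control
(past-use) bias analysis* that measures how much confounding survives
covariate adjustment before any head-to-head comparison is interpreted.
The motivating application is the comparison of the two
thiazolidinediones, rosiglitazone and pioglitazone, on mortality and
cardiovascular outcomes.

Because the data sources this design was developed for (UK primary-care
records linked to hospital episodes and death certificates) are
proprietary, the package ships a synthetic EHR generator with known
ground truth. Every analysis stage is exercised, end to end, against
data whose true rate ratios, confounding structure and linkage pattern
are configured — so recovering the truth is a testable property rather
than an aspiration.

## Time conventions

All interval logic uses integer days and half-open intervals
`[start, end)`:

* current use: `[rx, rx + 91)` days after each prescription; overlapping
  windows merge, so a repeat prescription extends current use;
* recent use: `[last_rx + 91, last_rx + 365)`;
* past use: from `last_rx + 365` onwards; `never` before the first
  prescription;
* "one year after start of data collection" means
  `index >= data_start + 365` (inclusive);
* 1 y = 365 d, 3 y = 1095 d for life-table horizons; 30.44 d per month
  where month arithmetic is needed;
* age is computed from birth year with mid-year (July 1) birthdays, the
  convention for anonymised records that carry birth year only.

The 91/365-day reading of "3 months"/"12 months" keeps every window test
exact. Whether a repeat prescription *extends* or *restarts* the current
window is a design choice; extension is implemented (the merge rule
above). Past use is not capped.

A death on day *d* is represented as follow-up ending at `d + 1`, so the
death day itself contributes person-time and the event lies inside the
half-open follow-up interval.

## The synthetic generator

`scenario_config()` fixes the study conditions; `simulate_ehr()` draws
patients clustered in practices, prescriptions, outcomes, causes of
death and covariates. Design choices that matter:

* **Event times are exact.** All event generation inverts
  piecewise-constant hazards analytically within each constant piece —
  no discretisation — so calibration tests (events / person-years →
  configured hazard) are sharp at 3 Monte-Carlo standard deviations.
* **Confounding has one latent dial.** A standard-normal severity score
  enters initiation hazards of the channelled classes (insulin,
  sulphonylureas) and all outcome hazards log-linearly. Severity is
  written only to the ground-truth sidecar, never to the analysis
  tables; observed comorbidity flags are correlated with it, so
  covariate adjustment attenuates — but cannot eliminate — the
  confounding it creates. This is the simplest structure that gives the
  bias analysis something real to detect.
* **Calendar structure.** Default initiation multipliers make
  rosiglitazone uptake collapse after 2007 while pioglitazone rises,
  mirroring the late-2000s prescribing shift; analyses therefore face a
  real calendar-time imbalance that the calendar-year covariate must
  absorb.
* **Linkage.** A configurable fraction (default 40%) of practices is
  linked; hospital event records exist only for linked practices from
  April 1997, death-certificate causes only from January 2001. Analyses
  that need those sources restrict person-time accordingly.
* **Prescriptions.** Repeat prescriptions are issued every
  `prescription_cycle` days (default 60 — the interval is not dictated by
  the design and remains configurable) until a discontinuation time drawn
  from a per-class persistence hazard. A configurable fraction of
  thiazolidinedione prescriptions are fixed-dose combinations with
  metformin and enter both class histories.
* **Causes of death** are multinomial over ICD-10 chapters with a mix
  that may depend on the current drug class at death, so
  cause-of-death machinery can be tested against known truth.

What the generator does *not* emulate: dose and adherence, stockpiling,
switching driven by clinical response, free-text codes, regional
socioeconomic structure beyond a practice-level quintile, or real GPRD
marginals beyond the qualitative patterns above. Passing tests therefore
demonstrate correctness of the estimators under the generator's
assumptions, not fidelity of any specific real-world estimate.

## Cohorts and matching

The overall exposed cohort takes every non-type-1 adult of qualifying
age whose first antidiabetic prescription falls at least one year after
their data start (a prevalent-user cohort: earlier history is retained
but does not qualify). Inception cohorts per class require the
*first-ever* prescription of that class after the run-in; a patient may
enter several inception cohorts, which — together with time-dependent
classification — is what prevents immortal time bias. In head-to-head
contrasts each cohort is censored at the first prescription of the
comparator class.

Controls are matched 1:1 on practice, sex and age within 5 years, alive
and under observation at the exposed patient's index date with no prior
antidiabetic prescription, inheriting the index date. The matching rule
is nearest-age with seeded random tie-breaking: the design source states
the criteria but not a selection rule, and nearest-age maximises
comparability. A matched control who later starts an antidiabetic is
censored at that first prescription; whether such patients may also
appear as exposed elsewhere is not dictated by the design — they may,
and control person-time simply ends where exposure begins. Because every
patient in the simulated population is diabetic by construction,
eligible never-treated controls are scarcer than in a general-practice
population and a substantial unmatched fraction is expected and
reported, not an error.

## Person-time and rate models

`split_person_time()` cuts follow-up at every exposure-state change of
every class, every covariate change, every calendar-year boundary and
every age-band boundary, then coalesces adjacent segments with identical
labels. Covariate snapshots use the most recent value before segment
start; co-medication indicators use a 183-day lookback (≈ the 6-month
window conventional for "recent prescribing"). Age bands are
40–49, 50–64, 65–74, 75–84, 85+: the unequal 50–64 band lets the
below/at-65 stratification nest exactly within the bands.

`attribute_events()` counts each patient's first event of an outcome in
the containing segment. With `incident_only` (default), patients with a
record of that outcome before index contribute no person-time to that
outcome's analysis — never applied to death. Follow-up is truncated the
day after the first attributed event for every analysed outcome
(`censor_at_event = TRUE`); for death this is exactly the truncation at
the death date, and for non-fatal outcomes it is the standard
incident-rate convention.

Rates are contrasted with log-linear Poisson models with a
log-person-years offset, fitted by IRLS (relative tolerance `1e-10`,
at most 100 iterations; non-convergence is an error, never a silent
result). Person-time is aggregated over the cross-classification of the
model's covariates before fitting; by Poisson sufficiency this changes
nothing, and a test asserts exactly that. The minimal adjustment set is
age band, sex, calendar year (all categorical — assumption-light in the
absence of any stated functional form); the full set adds smoking,
alcohol and BMI (missing values as an explicit category, BMI cut at
25/30), comorbidity-history flags, recent co-medication indicators,
current-use indicators of the other drug classes, and the socioeconomic
quintile only when the analysis is restricted to linked practices (it is
undefined elsewhere; the restriction is logged). Confidence intervals
are Wald on the log scale with z = 1.96. Exact covariate codings (band
widths, BMI cut points) are documented defaults, configurable, and no
validation result depends on them. Levels with separated likelihoods
are flagged and reported with `[0, Inf)` limits rather than nonsense
Wald intervals.

## Duration-of-use hazards

Risk over duration of current use is described on a grid of 100
equal-width periods (equal in *time*; an equal-events alternative was
considered and rejected as harder to compare across arms) carrying
per-period events and person-time. The hazard is smoothed in the
Ramlau-Hansen manner: a kernel-weighted sum of the grid's Nelson-Aalen
increments,

$$\hat h(t) = \frac{1}{b}\sum_i K\!\left(\frac{t - t_i}{b}\right) \Delta\hat H_i,
\qquad \Delta\hat H_i = \frac{d_i}{Y_i},$$

with the per-period occurrence/exposure rate times the period width as
the increment. Defaults: Epanechnikov kernel, bandwidth 10 periods —
the method's source names the estimator but not its tuning, so both are
configurable. Boundary bias at 0 and at the maximum duration is handled
by reflection, which preserves the total cumulative-hazard mass (a test
requires interior mass preservation within 2%). The reported curve is
the *ratio of two separately smoothed hazards* — not a smoothed ratio —
an interpretation flagged as such; points where the denominator falls
below a floor are masked rather than propagated as infinities. With a
uniform kernel and sub-period bandwidth the smoother degenerates to the
raw per-period rates, which pins down the scaling.

## Life tables

Absolute risk over current use comes from Kaplan-Meier product-limit
estimation (ties: events before censorings), with Greenwood variance and
log(−log) confidence intervals for the cumulative incidence
`100·(1−S(h))` at 1 and 3 years. Spells end at the event, at censoring,
or at exit from current use — the end-at-exit reading of an ambiguity in
the design (an intention-to-treat-like alternative would continue past
exit; the choice is config-visible in the spell extraction). Excess
risk is the difference of cumulative incidences computed at full
precision and rounded only for display. The composite endpoint is
time-to-first of death/ACS/stroke/heart failure, and its cumulative
incidence must dominate each component's on the same cohort — a tested
invariant. Competing-risk (Aalen-Johansen) estimation is deliberately
out of scope: the method reproduced here is the Kaplan-Meier life table,
and its known upward bias for non-fatal outcomes in the presence of
death is a documented limitation.

## The four analysis sets

`run_study()` chains the stages: (1) the past-use bias analysis — each
class's past-use person-time against matched controls and against past
metformin, minimally and fully adjusted; persistent fully-adjusted
departures from 1 are flagged as residual-confounding signals; (2) the
head-to-head current-use comparison (default rosiglitazone vs
pioglitazone) per outcome and data source, overall and stratified by
age (<65/≥65), current insulin co-prescribing, and calendar time split
at 2007; (3) the smoothed duration-of-use hazard ratio; (4) Kaplan-Meier
life tables with excess risks, overall and by age band and sex; plus the
cause-of-death table by ICD-10 chapter over a shared current-use
person-time denominator restricted to linked practices in the
death-certificate window.

The design principle that head-to-head comparisons are only interpreted
between drugs *without major past-use differences* is operationalised as
a configurable gate: the fully adjusted past-use death rate ratio of the
contrast must have a confidence interval covering 1 (`bias_gate()`,
tolerance 1 by default — the source states the principle, not a cutoff).
A failing gate flags the set-2 report; it never suppresses it, and the
verdict travels with the results.

## Validation scenarios and problem sizes

`validation_scenario()` freezes the three reference experiments:

* **recovery** — no channeling, true current-use death rate ratio 1.2
  for rosiglitazone vs pioglitazone, thiazolidinedione-heavy prescribing
  over 2000–2008 with the late-decade calendar shift, 50,000 patients
  (≈180 deaths in the contrast per replicate). The acceptance suite runs
  50 seeded replicates and requires the fully adjusted 95% CI to cover
  the truth in at least 42.
* **channeling** — severity-to-insulin coupling of 1.0 with no true drug
  effects: the past-insulin vs past-metformin death contrast must show a
  crude rate ratio above 1 that adjustment attenuates but does not
  eliminate, because severity itself is unobserved.
* **no_channeling** — the same population with the coupling removed:
  fully adjusted past-use rate ratios must be compatible with 1.

Other tests use populations of 200–20,000 patients, chosen as the
smallest sizes at which the property under test is informative (e.g.
the cause-of-death scenario uses a fully linked, thiazolidinedione-heavy
population so chapter-specific death counts are non-trivial).
Oracle-equivalence tests compare against independent reimplementations:
a day-resolution exposure classifier, brute-force risk-set products for
Kaplan-Meier (agreement to 1e-12), the analytic two-group rate ratio
(exact), and derivative-free likelihood maximisation for adjusted
Poisson fits (1e-6).

## Known limitations

* The generator's missingness is completely at random; the analysis
  handles missing lifestyle values as explicit categories, as the design
  prescribes, but no imputation is provided.
* No dose, adherence or switching dynamics; exposure is prescriptions,
  not ingestion.
* Kaplan-Meier cumulative incidence for non-fatal outcomes ignores the
  competing risk of death.
* The Poisson models use no practice-level random effects or robust
  variance; practice enters only through matching and the socioeconomic
  quintile.
* Constant true rate ratios within current use: the duration-dependent
  (early-excess) validation is performed at spell level against the
  smoothing pipeline directly.
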