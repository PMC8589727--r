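---
title: "Measuring antithrombotic utilisation, adherence and persistence from prescription records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring antithrombotic utilisation, adherence and persistence from prescription records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(thrombadhere)
library(dplyr)
```

This vignette is the package's account of its methods: the algorithms,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the methodology was genuinely open.

## Study design

The unit of analysis is a patient-drug-class pair. A patient enters the
anticoagulant cohort at their first (incident) atrial fibrillation
diagnosis and the antiplatelet cohort at their first myocardial
infarction, peripheral arterial disease, unstable angina or transient
ischaemic attack; the two cohorts are processed independently and a
patient may be in both. For patients with prevalent liver disease (any of
ALD, autoimmune liver disease, cirrhosis, HBV, HCV, NAFLD), the
indication must fall strictly *after* the first liver diagnosis: at day
resolution the ordering of same-day events is unknowable, so same-day
ties are excluded rather than guessed. The cohort is restricted to adults
aged 30 or over at the indication date — the indication is the analytic
entry point, so the age restriction is anchored there.

The new-user (drug-naive) restriction removes anyone with a same-class
prescription strictly before the indication; prescriptions of the other
class do not disqualify, since the two classes are analysed as separate
exposures. Follow-up runs from the indication to the earliest of primary
endpoint, death, last practice data collection, deregistration, or
administrative censoring (default 2020-06-30). Same-day ties are labelled
by the fixed priority endpoint > death > last collection > deregistration
> administrative censoring; the label affects only the recorded reason,
never the date.

## Prescribing prevalence

Prevalence per 100 persons uses the normal-approximation (Wald) interval,

$$100 \cdot \left(\hat p \pm z \sqrt{\hat p (1-\hat p)/n}\right),\qquad \hat p = k/n,$$

clipped to [0, 100]. The Wald form — rather than Wilson or exact
intervals — is deliberate: it is the central-limit-theorem interval for a
dichotomous outcome, which is what large-denominator prescribing studies
report, and it reproduces their printed limits digit for digit.
Degenerate cells ($k = 0$ or $k = n$) get a zero-width interval and a
`degenerate` flag rather than a silently misleading bound. Rounding is
half-up to one decimal and applied only at presentation
(`format_percent()`); base R's round-half-to-even would fail to reproduce
printed rates.

The numerator counts members with at least one same-class prescription
on or after the indication date, at any time during follow-up by default
(`within_followup = TRUE` restricts it). Patients with several liver
subtypes count in every subtype stratum, so subtype numerators may exceed
the liver-disease total; that is a property of the stratification, not a
bug.

## Supply episodes and PDC

Prescription records carry issue dates only, so supply is modelled: every
issue opens `supply_days` (default 30) days of cover, truncated at the
next issue of the same stream if it arrives earlier. The truncation means
early refills never stockpile; this is forced by the episode-duration
rule rather than chosen. Same-day duplicate issues collapse to one,
because the duration rule would otherwise assign them zero days.
Intervals are half-open `[start, end)` and all arithmetic is in integer
day offsets, which removes every off-by-one ambiguity in the PDC and gap
computations.

PDC over a window of `window_days` (183 for 6 months, 365 for 12 months
— calendar-faithful integers, both configurable) is the total episode
length intersected with `[index, index + window)` divided by the window.
Adherence is strict: PDC must *exceed* 0.80; a patient at exactly 0.80 is
non-adherent. Eligibility requires follow-up of at least the window and
more than one class prescription; patients with exactly one class
prescription are primary non-adherent and are reported as their own
outcome rather than given a PDC of 30/183.

Drug-level PDC uses only the index drug's issues; class-level PDC pools
all issues of the class into one episode stream (the union is the
conservative class-level reading — per-drug tables need the former,
"any anticoagulant" summaries the latter). Drug-level PDC does not
accumulate coverage from a post-switch drug; the switch is handled by the
persistence machinery instead.

The implementation is checked against a brute-force day-grid oracle (a
boolean array of the window, one cell per day) on a thousand random
prescription streams, with agreement required to $10^{-12}$.

## Persistence, gaps and switching

A patient discontinues when a supply gap of at least
`gap_threshold_days` (default 90, compared with `>=` because a gap "of 90
days" is reached at 90) opens between the end of assumed supply and the
next issue, or the end of follow-up when there is no next issue. The gap
is anchored at the supply end rather than the issue date (a 30-day supply
followed by 60 quiet days is a 60-day gap, not a 90-day one); the
`gap_from = "issue"` flag provides the other convention. The recorded
discontinuation date is the last supply end — the standard
pharmacoepidemiologic convention.

Switching to a different drug of the same class censors persistence
follow-up instead of counting as discontinuation. Two interactions needed
a decision:

- *A switch inside a pending gap.* The gap scan stops at the switch: a
  gap qualifies only if it reaches the threshold before the switch
  happens. A patient whose warfarin supply ends on day 30 and who starts
  rivaroxaban on day 70 is censored at the switch, not discontinued — the
  40 quiet days never reached 90.
- *Same-day tie.* If a qualifying discontinuation and a switch fall on
  the same day, the switch dominates (censoring is the conservative
  choice for a persistence estimate).

Landmark status at 6/12 months is decided by the earliest of
discontinuation, switch and end of follow-up; landmark denominators
include only patients with follow-up at least the landmark and exclude
primary non-adherers, and the joint adherence-by-persistence table keeps
censored patients in the denominator, which is how the printed
denominators of such tables are constructed. Raising the gap threshold
can only move patients toward persistence — a property test asserts the
monotonicity.

## Clinical scores

Child-Pugh components use the standard published thresholds (bilirubin
<2 / 2–3 / >3 mg/dL; albumin >3.5 / 2.8–3.5 / <2.8 g/dL; INR <1.7 /
1.7–2.3 / >2.3; ascites and encephalopathy graded none / mild / severe),
summed to 5–15 and classed A (5–6), B (7–9), C (10–15). Routine records
rarely grade ascites or encephalopathy, so a bare presence flag scores 2
points — an explicit, documented assumption. Any missing component
withholds the score entirely and names the component, rather than
imputing a best-case 1.

FIB-4 uses the standard four-input formula
$\mathrm{age} \times \mathrm{AST} / (\mathrm{platelets} \times \sqrt{\mathrm{ALT}})$
with strata <1.45, [1.45, 3.25] (closed at both printed cut points) and
strictly >3.25. Units are fixed per analyte in the table schema (mg/dL,
g/dL, U/L, 10⁹/L) — unit conversion rules are out of scope, and mixed
units would corrupt both scores silently.

CHA₂DS₂-VASc uses the standard weights (heart failure 1, hypertension 1,
age ≥75 2, diabetes 1, prior stroke/TIA 2, vascular disease 1, age 65–74
1, female 1) with strata 0–1 / 2 / 3–4 / 5–9. Laboratory values feed the
scores through a lookback window of 365 days before to 30 days after the
index date (both configurable); the nearest measurement to the index
wins.

## Rosendaal TTR

Between consecutive INR measurements the INR path is linear, so the
fraction of the interval in range [2, 3] equals the fraction of the
value shift inside the range; days in range accumulate as fraction ×
inter-measurement days. Boundaries are inclusive — the effect is
measure-zero except for series sitting exactly on a boundary, where
inclusion is the natural reading of "between 2 and 3". Time before the
first and after the last measurement is not interpolated and is excluded
from the denominator, and fewer than two in-period measurements leave TTR
undefined (`NA`) rather than zero. No maximum inter-measurement gap is
imposed by default (classic implementations often drop gaps over 56
days); `max_gap_days` exposes the exclusion. The assessment period
defaults to the 12-month adherence window from the index date and is a
parameter of `ttr_summary()`.

Correctness is checked two ways: an exact oracle that solves the
boundary-crossing times on each linear segment (agreement $10^{-12}$),
and a $10^{-3}$-day midpoint quadrature of the interpolated path's
in-range indicator. The quadrature's resolution bounds its own accuracy
at roughly half a step per boundary crossing, so the $10^{-6}$-level
comparison uses series with long inter-measurement spans (thousands of
days), where the bound is below $10^{-6}$; realistic 1–8-week spacing is
covered by the exact oracle instead.

## Risk models

The four model families are thin, opinionated wrappers around
`stats::glm` and `survival::coxph`: logistic non-adherence at 6/12
months, Cox non-persistence (switch and follow-up censored, with the
scaled-Schoenfeld proportional-hazards test attached), Cox stroke risk by
uncovered-time category, and Cox bleeding risk per 10-percentage-point
PDC. Reference levels follow the reporting convention of such studies —
warfarin/aspirin for drug, age 30–49, CHA₂DS₂-VASc 0–1, Child-Pugh A,
FIB-4 <1.45, uncovered time <1 week — and confidence intervals are Wald
intervals on the log scale.

Uncovered time is the follow-up minus covered days, categorised at 7 /
30 / 91 / 183 days; it is a fixed per-patient exposure summarised over
follow-up, because the tables such models feed present one category per
patient. A time-updated exposure variant is explicitly out of scope. The
stroke model optionally stratifies baselines by CHA₂DS₂-VASc stratum or
contrasts liver status within uncovered-time strata; the adjustment set
is an argument, not a hard-coded list, because published "adjusted"
hazard ratios rarely enumerate it.

Empty or single-level covariates are dropped with a warning rather than
crashing the fit, and changing a reference level rescales estimates by
exact ratios (tested). None of the models is expected to reproduce any
published coefficient — those depend on individual-level licensed data —
so the models are validated by parameter recovery: effects planted by the
generator (category hazard ratios of 0.5–2, a bleeding hazard ratio of
1.18 per 10% PDC, drug odds ratios of 0.5) must be recovered within
roughly 15% of truth at n = 20,000 (Cox) and n = 5,000 (logistic), and
null simulations must cover the null in at least 90% of replicates.

## The synthetic-EHR generator

The generator emulates the *structure* the analysis assumes, not any real
population: person-level linkage across the four tables; prevalent liver
disease (six subtypes, weights roughly proportional to the relative
denominators seen in liver cohorts) preceding the incident indication;
drug-naivety by construction (violations only when explicitly planted via
`p_pre_indication_rx`, to exercise the filter); refill streams drawn from
four archetypes; AR(1) INR trajectories for warfarin users sampled every
14–42 days; a five-analyte laboratory panel within 90 days of the
indication; exponential censoring; and stroke/bleeding events from
exponential hazards scaled by the configured category and PDC effects.

The archetypes are the key design choice: a single adherence distribution
tends to leave cells of the joint adherence-by-persistence table empty,
while archetypes (`primary_nonadherent` — exactly one issue;
`steady_refiller` — Normal(30, 5)-day intervals; `irregular_refiller` — a
65/35 mixture of short Normal(30, 5) and long Normal(80, 25) intervals;
`early_discontinuer` — a geometric number of steady refills, then
nothing) populate all of them by construction. The default archetype
weights (0.08 / 0.30 / 0.42 / 0.20) and prescribing probabilities (0.21
with liver disease, 0.335 without) were set once, a priori, to the
marginal conditions of the population the pipeline targets — a primary
non-adherence share near 8%, 12-month adherence near a third, 12-month
persistence near two thirds, and lower prescribing in liver disease — and
are not tuned thereafter. The INR process defaults
(mean 2.5, sd 0.5, lag-1 autocorrelation 0.6) put typical TTR values on
both sides of the 60% covariate cut.

What the generator does **not** emulate: realistic UK geography (regions
are a uniform draw), correlated comorbidity structure beyond what the
scores need, dose information, seasonal prescribing, or informative
censoring. Passing tests therefore demonstrate the *algorithms* are
correct under the stated data model, not that any epidemiologic estimate
from real data would be unbiased.

Determinism: every stochastic step flows from one integer seed via R's
Mersenne-Twister; identical configuration and seed give byte-identical
CSV output, which the tests assert with file checksums.

## Problem sizes and runtime choices

The test suite exercises cohorts of 300–1,000 synthetic patients for
structural checks, 1,000 random streams/series for the oracle
comparisons, 20,000 patients for Cox parameter recovery and 100
replicates of n = 5,000 for logistic coverage; these sizes put Monte
Carlo error well inside the stated recovery brackets while keeping a full
run to a couple of minutes. The acceptance script uses the same sizes.

## Known limitations

- Supply duration is a blanket constant; quantity/duration fields, when
  present in source data, are ignored by design.
- Over-the-counter aspirin is invisible to prescription records, so
  antiplatelet non-adherence can be overstated; nothing in the package
  corrects for it.
- The condition vocabulary is a closed enumeration standing in for
  code-list phenotypes; a code-list-to-condition mapping layer is the
  declared extension point and ships empty.
- Re-initiation after a qualifying gap ("restarters") is not analysed;
  the first qualifying gap is terminal for persistence.
- Multiple imputation is not performed anywhere; missingness withholds
  scores and excludes patients from the affected analysis.
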