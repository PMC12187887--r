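---
title: "Phenotyping maintenance immunosuppression from claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping maintenance immunosuppression from claims: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(txtrace)
library(dplyr)
```

## The problem

Kidney transplant recipients take maintenance immunosuppression for life.
National insurance claims record every reimbursed community-pharmacy
delivery and every hospital stay, but they record neither clinical intent
nor outcomes: there is no field that says "this patient's graft failed" or
"this patient is on belatacept". Working with claims therefore means
phenotyping — turning raw delivery and hospitalization streams into
regimens, switches, and graft outcomes through explicit, auditable rules.

`txtrace` implements that rule set as a pipeline of data-frame
transformations:

1. **Cohort**: find each patient's first transplant hospitalization
   (procedure codes `JAE003`/`HNEA002` by default), apply eligibility rules
   (adult, documented sex, present in the database during the prior year,
   no data inconsistencies), and flag baseline comorbidity and
   transplant-history indicators.
2. **Exposure**: convert deliveries into per-class coverage episodes,
   partition follow-up into regimen periods, detect combinations, switches
   and add-ons, and identify belatacept use from infusion-stay patterns.
3. **Outcomes**: date graft loss through a proxy (treatment gap,
   retransplantation, or sustained dialysis resumption) and assemble
   competing-risk outcome records.
4. **Estimation**: Kaplan-Meier overall survival and Aalen-Johansen
   cumulative incidence of graft failure with death as the competing risk,
   overall and by age class.

Because no real claims extract can ship with the package, a synthetic-data
generator with per-patient ground truth is a first-class module: every
downstream rule is tested by generating claims whose truth is known and
asking whether the pipeline recovers it.

## Exposure model

A delivery of class $c$ on day $d$ (days from the index transplantation)
grants coverage over the half-open interval $[d, d + \text{coverage})$.
Coverage windows of the same class separated by at most `merge_gap_days`
are merged into one episode. All intervals in the package are half-open in
integer days, which makes gap arithmetic unambiguous.

Two parameters govern this model and neither is observable in claims, so
both are configuration with defaults chosen once:

* `coverage_days = 30` — one delivery covers one month. French community
  pharmacies dispense chronic medication in (roughly) monthly packs; 30
  days is the standard assumption in claims research when pack sizes are
  unknown.
* `merge_gap_days = 31` — a refill up to a month late continues the same
  episode. This absorbs stockpiling jitter without bridging true
  discontinuations.

Everywhere a rule speaks in months, a month is 30 days and three months is
91 days. This convention is stated once in `code_config()` so sensitivity
analyses can vary it.

### Regimen periods and combinations

Follow-up is partitioned into maximal periods of constant covered-class
set. A period with more than one molecule class lasting **under 30 days**
is treated as transition slack and absorbed into the adjacent
(preferentially preceding) period: a 25-day overlap between an outgoing
and an incoming drug is a handover, not a combination. A surviving
multi-drug period counts as a combination regimen only when its
non-steroid class-group set (CNI, antimetabolite, mTOR inhibitor,
belatacept) is in the configured list of recognised regimens.
Corticosteroids never affect recognition — they accompany nearly every
backbone and carry no information about it.

### Switches and add-ons

When a non-steroid class starts a new coverage episode after the
90-day initial-regimen window, the event is classified by what the
previous classes do next: if every class covered on the previous day
retains at least 30 days of coverage alongside the newcomer, the event is
an **add-on**; otherwise it is a **switch**, dated at the relay class's
first delivery. The 30-day tie (exactly 30 residual days) resolves as
add-on because the rule is inclusive. Class starts inside the first 90
days are initial-regimen accrual, not relays: a patient whose
mycophenolate starts five days after tacrolimus is starting a combination,
not switching.

### Belatacept

Belatacept is infused in hospital and (before retrocession) invisible in
community-pharmacy claims, so exposure is inferred from a three-clause
pattern: (1) at least three hospitalizations for chemotherapy delivery for
a non-tumoral disease carrying a kidney-transplant diagnosis code, with
admission dates spanning at most 90 days — the earliest stay of the
earliest qualifying window is the *index hospitalization*; (2) at least
one mTOR-inhibitor or antimetabolite delivery within 90 days (inclusive)
of the index hospitalization; (3) no CNI delivery during the fourth month
after it. The "fourth month" is encoded as the half-open day interval
$[91, 121)$ — fixed 30-day months keep the rule deterministic where
calendar months are ragged. Two clauses were genuinely open to
interpretation and are resolved as follows, both configurable:

* the companion delivery window is $[\text{index hosp}, +90\,\text{d}]$,
  not $\pm 90$ days — a companion drug before the first infusion would be
  evidence about the *previous* regimen;
* "no delivery of a CNI" refers to community deliveries, the only CNI
  source visible in the data.

A delivery whose ATC code maps directly to belatacept (retrocession-era
data) short-circuits to a positive call. For positive patients the
qualifying infusion stays are also converted into timeline episodes
(`belatacept_episodes()`) so that the combination, switch and graft-loss
rules see belatacept like any community-dispensed class — otherwise a
switch *to* belatacept would be invisible.

## Graft-loss proxy

Graft failure is dated at the earliest of:

a. **treatment gap** — the end of all-class immunosuppressive coverage
   followed by more than 91 days with no delivery, dated at the coverage
   end (the clock starts at coverage end, not at the last delivery, so the
   rule composes with `coverage_days`);
b. **retransplantation** — admission date of a later transplant-coded stay;
c. **dialysis resumption** — first session of a post-index dialysis run
   spanning at least 91 days with no inter-session gap above
   `dialysis_gap_days = 45` (1.5 times the monthly session cadence the
   generator emits; maintenance dialysis in the real world is far denser,
   so any tolerance between "same run" and "three months" is defensible —
   what matters is that it is one documented constant).

A silent window cut short by death or by the administrative study end does
not qualify: absence of claims after death is not treatment
discontinuation. Same-day graft loss and death is coded as **death** —
death is the competing risk of interest, and terminal hospitalizations
would otherwise manufacture spurious graft losses. Loss to follow-up,
undefined in claims, is operationalized as more than 365 days of all-claim
silence ending before the study end; the patient is censored at the last
claim.

## Survival estimation

`km_fit()` and `aj_fit()` wrap `survival::survfit()`: the product-limit
estimator with Greenwood variance and a log-log-transformed 95% band
(plain Greenwood is available through `conf_type`), and the multi-state
Aalen-Johansen estimator of cause-specific cumulative incidence with its
standard counting-process variance. The Aalen-Johansen identity
$F_{\text{graft}}(t) + F_{\text{death}}(t) + S(t) = 1$ holds to $10^{-10}$
at every event time and is asserted in the tests. Ties across causes at
the same time are processed against the same pre-time risk set. Times are
kept in years (days divided by 365.25). The test suite checks both
estimators against brute-force risk-set recomputation at every distinct
event time, so the wrapper is never trusted blindly.

The overall-survival estimand treats death as the event with follow-up
censored at graft loss and study end; the graft-survival estimand is
$1 - F_{\text{graft}}(t)$ from the competing-risks fit. A retransplant-only
variant of graft loss can be obtained by configuring the treatment-gap and
dialysis thresholds out of reach.

## What the generator emulates — and what it does not

`simulate_claims()` emits, per patient: an index transplant stay, a
pre-index presence claim, pre-index dialysis (87% of patients; the rest
are pre-emptive), roughly monthly deliveries of the regimen's classes,
infusion-stay triplets (with antimetabolite companion and no CNI) for
belatacept patients, dialysis resumption after graft failure, and death
dates. Event times are sampled from constant cause-specific hazards —
exponentials make closed-form answers available
($F_k(t) = \frac{\lambda_k}{\lambda}\,(1 - e^{-\lambda t})$ with
$\lambda = \lambda_g + \lambda_d$), so estimator recovery can be tested
against analytic truth rather than against another estimator.

The default hazards are calibrated so the true 5-year quantities equal the
published national estimates: $\lambda_d = 0.023306$/year gives
$S(5) = e^{-5\lambda_d} = 0.890$, and $\lambda_g = 0.034550$/year gives a
5-year graft-failure cumulative incidence of $0.150$, i.e. graft survival
$0.850$. Age-class weights (6.8/12.4/19.1/24.9/24.7/12.1%), a 62.7% male
fraction, a 3.9% belatacept fraction and a regimen mix dominated by
tacrolimus + mycophenolate + corticosteroid echo the published cohort
description. The per-year switching intensity of 0.065 with a one-year
floor between successive changes reproduces the reported order of
magnitude of switching (about a quarter of patients over a median four
years of follow-up) while keeping successive changes phenotypically
separable.

Determinism is strict: each patient draws from a substream seeded by a
fixed mix of the global seed and the patient counter, so patient $i$'s
claims are byte-identical whether the cohort has 15 or 15,000 patients.

Two deliberate identifiability constraints make zero-noise recovery exact
rather than merely close, and both mirror real limits of the proxy rules:

* a graft failure sampled within `treatment_gap_days + 2 * coverage_days`
  of the censoring horizon is emitted as censored in both truth and claims
  — a 3-month-gap rule cannot see a loss that close to the end of data;
* belatacept (initially or as a relay) is only assigned when at least 121
  days of observation remain, the span the three-stay clause and the
  fourth-month veto need to be evaluable.

What the generator does **not** emulate: real coding dictionaries beyond a
small default map, seasonal and pandemic effects, induction therapy,
hospital-delivered drugs other than belatacept, dose changes, and
informative censoring. Passing the zero-noise recovery suite therefore
shows the rules are implemented as specified, not that they are robust to
real-world miscoding; `corrupt_bundle()` exists to measure that robustness
(dropped deliveries, delayed deliveries, non-qualifying chemotherapy
stays) against the unchanged truth.

## Degenerate inputs and tie-breaks

* Two transplant stays with the same admission date collapse to one index
  event; exclusion reasons are attributed to the first failing rule in the
  order under-18, missing sex, absent prior year, inconsistent data, so
  the flow report partitions the screened population.
* Unknown ATC codes classify as `other` and never fail; `other` deliveries
  count for database presence and loss-to-follow-up but never for exposure.
* Patients with no deliveries and a negative belatacept call have an empty
  initial regimen ("no documented immunosuppressive treatment") — with
  in-hospital death soon after transplantation this genuinely occurs.
* An all-censored sample gives a degenerate Aalen-Johansen fit
  (survival 1, incidence 0) rather than an error; empty strata are
  skipped with a warning.
* `n_patients = 0` yields a valid empty bundle; an empty cohort runs the
  whole pipeline and yields empty tables.

## Problem sizes

The test suite validates estimators against brute-force oracles at 5,000
records, the belatacept algorithm against exhaustive triple enumeration on
streams of up to 20 stays, and full zero-noise recovery on a
10,000-patient simulation; the acceptance script fits single cohorts of
16,139 subjects. A worked small example:

```{r example}
sim <- simulate_claims(sim_config(n_patients = 400, seed = 19))
report <- run_pipeline(sim$bundle)
report

report$outcome_table |>
  select(stratum, n, surv, graft_surv) |>
  head()
```

## Known limitations

The phenotyping rules inherit every blind spot of their source data: early
graft losses and deaths before the first community delivery leave no
regimen trace; belatacept identification rests on a coding pattern that
cannot be validated against charts from inside the data; the graft-loss
proxy conflates discontinuation for any reason with graft failure when no
dialysis or retransplantation follows; and events in the last three months
before the administrative horizon are systematically unobservable. The
estimators themselves assume censoring is non-informative, which
loss-to-follow-up in claims may violate.
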