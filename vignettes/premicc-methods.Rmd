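---
title: "Validating a prognostic score for mild Crohn's disease: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a prognostic score for mild Crohn's disease: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premicc)
```

## The problem

The course of newly diagnosed Crohn's disease (CD) is highly variable:
roughly a quarter to a third of patients follow a mild, nonprogressive
course that can be managed with mesalazine and watchful monitoring, while
the rest need escalation to steroids beyond induction, immunosuppressants,
biologics, or surgery. Identifying the mild group at diagnosis would spare
those patients the cost and side effects of immunosuppressive therapy.

The PreMiCC score addresses this with five parameters that are available at
the first diagnostic work-up:

| Parameter | Finding | Points |
|---|---|---|
| Age at first diagnosis | ≤ 40 y | 1 |
| CRP (mg/dL) | < 2 | 0 |
|  | 2–4 | 1 |
|  | > 4 | 2 |
| Endoscopic score (worst segment, 0–4) | > 1 | 1 |
| Perianal lesions | yes | 1 |
| Complications (stenosis, fistula, EIM, fever > 38 °C) | ≥ 1 | 1 |

The total ranges from 0 to 6; a total of **2 or fewer predicts a mild
course**. This package implements the score, the treatment-escalation
outcome definitions of its prospective validation design, and the complete
time-to-event validation machinery, together with a synthetic
inception-cohort generator so the whole pipeline is testable without
patient-level data (which for the original cohort are not publicly
available).

### Scoring conventions

* The CRP bands are printed as "< 2", "2–4", "> 4". We read the middle band
  as the closed interval [2, 4], so the three bands partition the
  nonnegative axis; 2.0 and 4.0 both score one point. CRP stays in the
  input unit (mg/dL) with no conversion, even though the validation
  cohort's median of 14.4 "mg/dL" in the high-score group is
  physiologically more typical of mg/L; the ambiguity is inherited from the
  source data and deliberately not resolved here.
* The endoscopic input is the already-reduced severity of the worst bowel
  segment (ordinal 0–4); per-segment data are not modelled.
* Missing covariates are rejected, not imputed: the design scores every
  patient at baseline.

## Eligibility screening

An inception cohort requires patients enrolled before treatment shapes the
course. The screen demands a diagnosis at most 42 days before inclusion
(we implement the six-week window inclusively, ≤ 42 days, and note that
stricter "< 6 weeks" phrasings exist), and either no prior therapy or a
single short course (≤ 10 days) of mesalazine, budesonide or prednisolone;
emergencies needing immediate intensified therapy, patients needing
inpatient care, those with a clear surgical indication and those with
complicating infections are excluded, as are screening errors and consent
withdrawals. Rules are evaluated in a fixed order so the reported exclusion
reason is deterministic; multiple prior-therapy episodes are summed in
days. `apply_flow()` preserves the accounting identity
`final = eligible − errors − withdrawals` for any input.

## Outcome definitions

All timestamps are integer study days from the baseline visit; months use
a fixed divisor of 30.4375 days throughout, so day 120 is exactly
120/30.4375 ≈ 3.94 months.

**Week-8 escalation** (day 56): the patient escalated if they (1) received
therapy other than mesalazine, (2) were not steroid-free for the two weeks
before the assessment (any budesonide or systemic-steroid exposure
overlapping days 43–56), (3) started an immunosuppressant or biologic, or
(4) underwent CD-related surgery, all within days 0–56. Note that under
(1), steroids are judged by rule (2) and immunomodulators by rule (3), so
rule (1) effectively catches drug classes outside those groups;
IBD hospitalisation alone is not a week-8 criterion. Episodes entirely
after day 56 can never change the flag.

**Outcome failure** (the event in the time-to-event analysis): a steroid or
budesonide escalation, the initiation of immunosuppressive or biologic
therapy (any day), or IBD-related hospitalisation or surgery (any day).
The design permits induction steroids: a steroid course starting within
the first eight weeks and ending by day 42 is part of initial therapy and
is *not* a failure. A steroid exposure overlapping days 43–56 fails on its
first day inside that window (`max(start, 43)`), and any steroid course
starting after day 56 fails at its start. This is one defensible reading
of a design that adapts initial therapy and then assesses escalation at
week 8; the documentation flags it as a convention. Week-8 escalation does
not remove a patient from the time-to-event analysis — their failure time
is the underlying failure day.

Patients without a failure are censored at their last recorded visit.
Day-0 failures are clamped to 10⁻⁶ months so the product-limit code never
sees time zero.

## The survival stack

The Kaplan–Meier estimator, Greenwood variance and two-sample log-rank
test are implemented from first principles (they are the methodological
core being validated, and the tests cross-check them against an
independent implementation):

* Product-limit estimate S(t) = Π over event times tᵢ ≤ t of (1 − dᵢ/nᵢ),
  with the standard tie convention that events precede censorings at equal
  times; curves are stored at event times and evaluated between them as
  right-continuous steps.
* Greenwood variance S(t)² Σ dᵢ/(nᵢ(nᵢ − dᵢ)); confidence bands (default
  95%) on the log(−log) scale, which keeps them inside [0, 1].
* Unweighted log-rank: at each distinct event time the observed events in
  one group are compared with their hypergeometric expectation and
  variance d·(n₁/n)(1 − n₁/n)(n − d)/(n − 1); the statistic (O − E)²/V is
  referred to the upper tail of χ²(1), with no continuity correction.
  Risk sets of size one contribute zero variance.

## Diagnostic accuracy, ROC and group comparisons

The score is evaluated as a classifier of the observed course at fixed
horizons (defaults 36 and 48 months). The *positive* prediction is the
mild class (score ≤ 2) and the *condition positive* is an actually mild
course: no failure by the horizon with follow-up reaching it. Patients
censored before the horizon without an event carry no horizon label and
are excluded — a complete-case horizon analysis, chosen because the
source design does not state its handling. An event before the horizon
makes the course non-mild regardless of later follow-up. Sensitivity is
therefore P(score ≤ 2 | mild course), and the PPV is the probability of a
mild course given a low score. Undefined metrics (empty denominators) are
reported as `NA`, never silently zero; proportions get Wilson score
intervals.

The ROC sweeps "predict mild when total ≤ k" for k = −1…6 over the full
integer score and integrates by trapezoids, which equals the pairwise
concordance probability with ties counted one half. The reported AUC for
the dichotomised published score is internally inconsistent with the
printed 48-month sensitivity/specificity pair, so the package computes the
ROC over the full 0–6 score and makes no claim about reproducing that
printed AUC.

Odds ratios use the cross-product with a Woolf log-scale interval and the
Haldane–Anscombe 0.5 correction when a cell is empty, high-score group
first. Baseline tables are compared per variable with Pearson's chi-square
(no continuity correction), switching to Fisher's exact test when any
expected cell is 5 or below, and with the two-sided Wilcoxon rank-sum test
(normal approximation with tie correction) for numeric variables;
significance is flagged at p < .05 with no multiplicity adjustment,
mirroring per-variable baseline-table reporting practice.

## The synthetic cohort generator

Real patient-level data for the validation cohort are not deposited, so
the generator produces cohorts with the statistical structure the analysis
assumes; it is calibrated to the cohort's printed summary statistics, not
to patient-level realism.

* **Strata.** Defaults of 88 low-score (≤ 2) and 113 high-score (> 2)
  patients. Covariates are drawn to match the printed baseline marginals —
  low stratum: log-normal age around median 46 y, log-normal CRP around
  median 1.4 mg/dL, endoscopic categories weighted toward ≤ 1, rare
  flags; high stratum: median age ≈ 29 y, CRP ≈ 14.4 mg/dL, endoscopy
  weighted > 1, flags at the high-score column's frequencies. Records are
  rejection-resampled until they score into their intended stratum, so the
  scoring round-trip recovers the strata for 100% of records. Joint
  covariate structure is *not* modelled — marginal-median fidelity plus
  stratum consistency is the property the pipeline needs.
* **Event times.** Piecewise-exponential hazards sampled by inverting the
  cumulative hazard. The defaults are front-loaded (breakpoint at month 6)
  and calibrated in code so the cumulative escalation probability at month
  36 equals 24.2% (low stratum; early rate 0.03/month) and 70.2% (high
  stratum; early rate 0.13/month), placing more than half of all events
  within the first six months. The pooled figure of 29.5% escalation-free
  at 36 months is arithmetically inconsistent with the stratified pair, so
  it gets its own single-arm scenario (`cohort_config_pooled()`, constant
  hazard −log(0.295)/36 per month); the two calibrations are never mixed.
* **Censoring.** Administrative censoring at month 60 plus a small
  exponential dropout (0.004/month; the source reports a mean follow-up of
  38.4 months but no censoring distribution, so this is an assumption).
  The censoring time is snapped to the visit grid (0, 3, 6, 9, 12, 18, 24,
  30, 36, 48, 60 months — quarterly in year one, six-monthly to year
  three, then annually) because an observational cohort only sees patients
  at scheduled visits; we snap to the next scheduled visit, capped at the
  administrative month, which slightly favours observing events that fall
  just after a dropout.
* **Realization.** A planned failure becomes, by default, a biologic
  episode starting on the planned day, so the event classifier recovers
  the planned time exactly (the round-trip is property-tested); a
  configurable mix allows steroid, surgery or hospitalisation
  realizations, with steroid realizations of failures planned on or before
  day 56 falling back to biologics to keep the planned day recoverable.
  One seeded generator drives each run and the seed is recorded in the
  output metadata; identical configuration and seed give byte-identical
  CSV output.

Passing tests on these cohorts demonstrates that the pipeline's estimators
recover known generating parameters under realistic censoring; it cannot
demonstrate calibration to real CD cohorts, joint covariate realism, or
robustness to data-quality problems real registries have.

## Numerical and reporting choices

* Month conversion fixed at 30.4375 days/month everywhere.
* KM tie handling: events before censorings; p-values from χ²(1) upper
  tails; confidence level defaults to 0.95.
* Percentages are rounded to one decimal only in human-readable output;
  JSON reports keep full precision.
* Simulation-based checks in the test suite use 500 replicate cohorts at
  the study's group sizes (88/113/201), which puts Monte-Carlo standard
  errors of recovered proportions near 0.2 percentage points.

## Worked example

```{r example, eval = FALSE}
ds <- generate_cohort(cohort_config(seed = 7))
report <- run_validation(ds)
report
render_report(report, "report", formats = c("json", "csv"))
```

## Known limitations

* The escalation-beyond-induction convention for steroids (above) is one
  reading of the design; alternative readings shift a small number of
  early failure times.
* The complete-case horizon 2×2 ignores informatively censored patients.
* The generator draws covariates independently within stratum; any
  analysis of covariate *correlations* on synthetic data is meaningless.
* No Cox regression, covariate adjustment, weighted log-rank variants,
  time-dependent ROC or calibration curves: the validation design uses
  none of these.
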