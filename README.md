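# premicc

Tools for computing and validating the **PreMiCC** score — a 0–6 point
prediction score for a *mild course* of newly diagnosed Crohn's disease
(CD) — against longitudinal treatment-escalation outcomes.

## The problem and the score

The course of incident CD is highly variable: a substantial minority of
patients (about 20–30%) never need escalation beyond conventional therapy
(mesalazine, possibly short induction steroids), while the rest go on to
immunosuppressants, biologics, surgery or hospitalisation. A reliable
baseline predictor of the mild group lets clinicians avoid overtreatment.

The PreMiCC sums five diagnosis-time parameters:

    points = [age ≤ 40 y] + crp_band(CRP) + [endoscopic score > 1]
             + [perianal lesions] + [≥ 1 complication]

where `crp_band` is 0 for CRP < 2 mg/dL, 1 for 2–4 and 2 for > 4, and
complications are stenosis, any fistula, extraintestinal manifestation or
fever > 38 °C. A total ≤ 2 predicts a mild course.

The package implements, from first principles where the methodology is the
point:

* `scoring` — component points, total, risk classification;
* `cohort_io` — CSV schemas for baseline/therapy/events/visits tables,
  eligibility screening and study-flow accounting;
* `events` — the week-8 escalation flag and time-to-first-failure records
  (months at 30.4375 days/month);
* `survival` — Kaplan–Meier product-limit estimation with Greenwood
  variance and log(−log) bands, and the two-sample log-rank test;
* `diagnostics` — horizon 2×2 classification, sensitivity/specificity/
  PPV/NPV with Wilson intervals, ROC/AUC over the integer score, odds
  ratios, baseline-table comparisons (chi-square / Fisher / Wilcoxon);
* `synthetic_data` — a seeded inception-cohort generator with
  score-stratified covariates and front-loaded piecewise-exponential
  escalation hazards calibrated to the validation study's printed rates;
* `pipeline` — `run_validation()` / `render_report()` tying it together.

See `vignettes/premicc-methods.Rmd` for the model, conventions and design
choices.

## Worked example

```r
library(premicc)
ds <- generate_cohort(cohort_config(seed = 7))   # 88 low / 113 high score
report <- run_validation(ds)
report
```

```
PreMiCC validation report
  patients: 201 (score <=2: 88, score >2: 113)
  week-8 escalation: 16.4% overall (6.8% / 23.9% in score <=2 / >2)
  escalation by month 12: 16.1% (score <=2) vs 55.1% (score >2)
  escalation by month 24: 18.5% (score <=2) vs 63.6% (score >2)
  escalation by month 36: 24.6% (score <=2) vs 66.5% (score >2)
  log-rank: chi-square = 43.20, p = 4.94e-11
  at 36 months: sensitivity 64.2%, specificity 77.9%, PPV 74.4%, NPV 68.5%
  at 48 months: sensitivity 69.0%, specificity 78.6%, PPV 72.5%, NPV 75.7%
  ROC AUC (horizon 36 months): 0.761
```

Reading the output: the generator draws a cohort whose low/high-score
strata escalate with 36-month cumulative probabilities calibrated to 24.2%
and 70.2%; the Kaplan–Meier estimates recovered by the pipeline (24.6% vs
66.5% on this seed) agree up to sampling noise, the strata diverge
decisively on the log-rank test, and the score discriminates the observed
36-month course with AUC ≈ 0.76. `render_report(report, "report")` writes
`report.json` plus per-stratum KM tables and the comparison tables as CSV;
`formats = c("json", "csv", "plots")` adds PNG figures.

A thin CLI over the same functions is installed with the package
(`system.file("scripts", "premicc", package = "premicc")`) with
subcommands `screen`, `score`, `simulate` and `validate`.

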