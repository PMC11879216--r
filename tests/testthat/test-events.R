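dpm <- 30.4375

test_that("week-8 escalation criteria fire as defined", {
  expect_false(assess_week8_escalation(tl(ep("mesalazine", 0, 56))))
  expect_true(assess_week8_escalation(tl(ep("systemic_steroid", 0, 50))))
  expect_true(assess_week8_escalation(tl(ep("biologic", 30))))
  expect_true(assess_week8_escalation(tl(ep("immunosuppressant", 56))))
  expect_true(assess_week8_escalation(tl(ep("other", 10, 20))))
  # induction steroids ending before the steroid-free window are permitted
  expect_false(assess_week8_escalation(tl(ep("budesonide", 0, 42))))
  expect_true(assess_week8_escalation(tl(ep("budesonide", 0, 43))))
  # surgery counts, hospitalisation does not (week-8 rules only)
  expect_true(assess_week8_escalation(tl(events = ev("cd_surgery", 40))))
  expect_false(assess_week8_escalation(
    tl(events = ev("ibd_hospitalization", 40))))
})

test_that("episodes entirely after day 56 never affect the week-8 flag", {
  quiet <- tl(ep("mesalazine", 0, 56))
  for (late in list(ep("biologic", 57), ep("systemic_steroid", 60, 90),
                    ep("other", 100, 200))) {
    expect_equal(assess_week8_escalation(tl(ep("mesalazine", 0, 56), late)),
                 assess_week8_escalation(quiet))
  }
})

test_that("derive_failure picks the earliest failure with exact month time", {
  r <- derive_failure(tl(ep("biologic", 120)))
  expect_true(r$event)
  expect_equal(r$time_months, 120 / dpm)
  expect_equal(round(r$time_months, 2), 3.94)
  expect_equal(r$failure_kind, "immunomodulator_biologic")

  r <- derive_failure(tl(ep("mesalazine", 0)))
  expect_false(r$event)
  expect_equal(r$time_months, 1460 / dpm)
  expect_equal(round(r$time_months, 2), 47.97)

  # day-0 surgery is clamped to a small positive time
  r <- derive_failure(tl(events = ev("cd_surgery", 0)))
  expect_true(r$event)
  expect_equal(r$time_months, 1e-6)

  # induction steroid ending by day 42 is not a failure
  expect_false(derive_failure(tl(ep("systemic_steroid", 0, 42)))$event)
  # steroid overlapping the day 43-56 window fails at the window entry
  r <- derive_failure(tl(ep("systemic_steroid", 0, 50)))
  expect_true(r$event)
  expect_equal(r$time_months, 43 / dpm)
  # steroid starting inside the window fails at its start
  r <- derive_failure(tl(ep("budesonide", 50, 70)))
  expect_equal(r$time_months, 50 / dpm)
  # steroid starting after week 8 fails at its start
  r <- derive_failure(tl(ep("systemic_steroid", 200, 220)))
  expect_equal(r$time_months, 200 / dpm)
  expect_equal(r$failure_kind, "steroid")

  r <- derive_failure(tl(events = ev("ibd_hospitalization", 300)))
  expect_equal(r$failure_kind, "hospitalization")
  expect_equal(r$time_months, 300 / dpm)
})

test_that("derive_failure equals a brute-force day scan on random timelines", {
  oracle_day <- function(timeline, w8 = 56, win = 43) {
    ep <- timeline$episodes
    evs <- timeline$events
    stop_eff <- ifelse(is.na(ep$stop_day), timeline$last_contact_day,
                       ep$stop_day)
    steroid <- ep$drug_class %in% c("budesonide", "systemic_steroid")
    for (d in 0:timeline$last_contact_day) {
      hit <- FALSE
      if (nrow(ep) > 0) {
        hit <- any(steroid & ep$start_day > w8 & ep$start_day == d) ||
          any(steroid & ep$start_day <= w8 & stop_eff >= win &
                pmax(ep$start_day, win) == d) ||
          any(ep$drug_class %in% c("immunosuppressant", "biologic") &
                ep$start_day == d)
      }
      if (!hit && nrow(evs) > 0) hit <- any(evs$day == d)
      if (hit) return(d)
    }
    NA_integer_
  }
  set.seed(99)
  drugs <- c("mesalazine", "budesonide", "systemic_steroid",
             "immunosuppressant", "biologic", "other")
  for (i in 1:40) {
    last <- sample(100:600, 1)
    n_ep <- sample(0:4, 1)
    eps <- if (n_ep > 0) {
      starts <- sample(0:last, n_ep, replace = TRUE)
      stops <- ifelse(stats::runif(n_ep) < 0.4, NA_real_,
                      pmin(starts + sample(0:200, n_ep, replace = TRUE),
                           last + 500))
      data.frame(drug_class = sample(drugs, n_ep, replace = TRUE),
                 start_day = starts, stop_day = stops)
    } else NULL
    evs <- if (stats::runif(1) < 0.4) {
      ev(sample(c("cd_surgery", "ibd_hospitalization"), 1),
         sample(0:last, 1))
    } else NULL
    timeline <- followup_timeline("PX", eps, evs, last)
    r <- derive_failure(timeline)
    d <- oracle_day(timeline)
    # note: an "other" episode is not an outcome failure, only a week-8 flag
    if (is.na(d)) {
      expect_false(r$event)
      expect_equal(r$time_months, last / dpm)
    } else {
      expect_true(r$event)
      expect_equal(r$time_months, if (d == 0) 1e-6 else d / dpm)
    }
  }
})

test_that("the tte dataset joins risk classes and keeps patient order", {
  ds <- generate_cohort(cohort_config(seed = 4))
  scores <- compute_score(ds$baseline)
  tte <- build_tte_dataset(ds, scores)
  expect_equal(nrow(tte), 201)
  expect_equal(tte$patient_id, sort(ds$baseline$patient_id))
  expect_equal(sum(tte$risk_class == "mild_predicted"), 88)
  expect_true(all(tte$time_months > 0))

  expect_error(build_tte_dataset(ds, scores[-1, ]), "no score for patient")

  empty <- cohort_dataset(ds$baseline[0, ])
  expect_equal(nrow(build_tte_dataset(empty, scores)), 0)

  one <- cohort_dataset(
    ds$baseline[1, ],
    visits = data.frame(patient_id = ds$baseline$patient_id[1], day = 1000))
  r1 <- build_tte_dataset(one, scores)
  expect_equal(nrow(r1), 1)
  expect_false(r1$event)
})
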