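test_that("eligibility rules fire in fixed order with named reasons", {
  expect_true(screen_eligibility(screening_rec())$eligible)
  expect_true(screen_eligibility(
    screening_rec(days_since_diagnosis = 10,
                  prior_therapy_kind = "mesalazine",
                  prior_therapy_days = 5))$eligible)
  # six-week window is inclusive of day 42
  expect_true(screen_eligibility(
    screening_rec(days_since_diagnosis = 42))$eligible)

  v <- screen_eligibility(screening_rec(days_since_diagnosis = 50))
  expect_false(v$eligible)
  expect_equal(v$reason, "diagnosis-window")

  v <- screen_eligibility(screening_rec(prior_therapy_kind = "prednisolone",
                                        prior_therapy_days = 14))
  expect_equal(v$reason, "prior-therapy")
  expect_equal(screen_eligibility(
    screening_rec(prior_therapy_kind = "other",
                  prior_therapy_days = 1))$reason, "prior-therapy")

  for (case in list(
    list(f = "emergency_case", reason = "emergency"),
    list(f = "inpatient_need", reason = "inpatient"),
    list(f = "surgery_indication", reason = "surgery"),
    list(f = "complicating_infection", reason = "infection"),
    list(f = "screening_error", reason = "screening-error"),
    list(f = "consent_withdrawn", reason = "consent"))) {
    args <- stats::setNames(list(TRUE), case$f)
    v <- screen_eligibility(do.call(screening_rec, args))
    expect_equal(v$reason, case$reason)
  }

  # earlier rule wins when several fail
  v <- screen_eligibility(screening_rec(days_since_diagnosis = 100,
                                        consent_withdrawn = TRUE))
  expect_equal(v$reason, "diagnosis-window")
  v <- screen_eligibility(screening_rec(screening_error = TRUE,
                                        consent_withdrawn = TRUE))
  expect_equal(v$reason, "screening-error")
})

test_that("rule-irrelevant fields never change the verdict", {
  base <- screening_rec()
  v0 <- screen_eligibility(base)
  # therapy days are irrelevant while the kind is none
  for (d in c(0, 5, 500)) {
    base$prior_therapy_days <- d
    expect_equal(screen_eligibility(base), v0)
  }
  expect_error(screen_eligibility(screening_rec(days_since_diagnosis = -1)),
               "days_since_diagnosis")
  expect_error(screen_eligibility(screening_rec(prior_therapy_kind = "x")),
               "prior_therapy_kind")
})

test_that("the study flow arithmetic holds, including the published counts", {
  recs <- do.call(rbind, lapply(1:217, function(i) {
    as.data.frame(screening_rec(patient_id = paste0("S", i),
                                screening_error = i <= 11,
                                consent_withdrawn = i > 11 & i <= 16))
  }))
  fc <- apply_flow(recs)
  expect_equal(fc$screened_eligible, 217L)
  expect_equal(fc$screening_errors, 11L)
  expect_equal(fc$withdrawals, 5L)
  expect_equal(fc$final_cohort, 201L)

  expect_equal(apply_flow(NULL)$final_cohort, 0L)
  clean <- do.call(rbind, lapply(1:10, function(i) {
    as.data.frame(screening_rec(patient_id = paste0("S", i)))
  }))
  expect_equal(apply_flow(clean)$final_cohort, 10L)
})

test_that("flow counts satisfy the conservation identity for random inputs", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(1:40, 1)
    recs <- do.call(rbind, lapply(seq_len(n), function(i) {
      as.data.frame(screening_rec(
        patient_id = paste0("S", i),
        days_since_diagnosis = sample(c(10, 60), 1, prob = c(0.8, 0.2)),
        screening_error = stats::runif(1) < 0.15,
        consent_withdrawn = stats::runif(1) < 0.15,
        emergency_case = stats::runif(1) < 0.1))
    }))
    fc <- apply_flow(recs)
    expect_equal(fc$final_cohort,
                 fc$screened_eligible - fc$screening_errors - fc$withdrawals)
    expect_gte(fc$final_cohort, 0)
  }
})

test_that("CSV round-trip is lossless for generated cohorts", {
  for (seed in c(5, 23)) {
    ds <- small_cohort(seed = seed)
    dir <- withr::local_tempdir()
    write_cohort(ds, dir)
    back <- read_cohort(dir)
    for (tab in c("baseline", "therapy", "events", "visits")) {
      expect_equal(back[[tab]], ds[[tab]], ignore_attr = TRUE)
    }
    expect_true(file.exists(file.path(dir, "metadata.json")))
    meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
    expect_equal(meta$seed, seed)
  }
})

test_that("schema violations are reported with table and row", {
  ds <- small_cohort(seed = 2)
  bad <- ds
  bad$baseline$age_years[2] <- -4
  expect_error(validate_cohort(bad), "baseline row 2.*negative age")

  bad <- ds
  bad$therapy <- rbind(bad$therapy,
                       data.frame(patient_id = "GHOST",
                                  drug_class = "biologic",
                                  start_day = 3, stop_day = NA_real_))
  expect_error(validate_cohort(bad), "therapy row .*unknown patient_id")

  bad <- ds
  bad$baseline <- rbind(bad$baseline, bad$baseline[1, ])
  expect_error(validate_cohort(bad), "duplicate patient_id")

  bad <- ds
  bad$baseline$crp_mg_dl <- NULL
  expect_error(validate_cohort(bad), "missing column")
})
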