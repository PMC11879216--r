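# shared builders for timelines, screening records and tiny cohorts

ep <- function(drug, start, stop = NA_real_) {
  data.frame(drug_class = drug, start_day = start, stop_day = stop,
             stringsAsFactors = FALSE)
}

ev <- function(kind, day) {
  data.frame(event_kind = kind, day = day, stringsAsFactors = FALSE)
}

tl <- function(..., events = NULL, last = 1460, id = "P1") {
  eps <- list(...)
  episodes <- if (length(eps) > 0) do.call(rbind, eps) else NULL
  followup_timeline(id, episodes, events, last)
}

screening_rec <- function(days_since_diagnosis = 10,
                          prior_therapy_kind = "none",
                          prior_therapy_days = 0,
                          emergency_case = FALSE, inpatient_need = FALSE,
                          surgery_indication = FALSE,
                          complicating_infection = FALSE,
                          screening_error = FALSE,
                          consent_withdrawn = FALSE,
                          patient_id = "S1") {
  list(patient_id = patient_id,
       days_since_diagnosis = days_since_diagnosis,
       prior_therapy_kind = prior_therapy_kind,
       prior_therapy_days = prior_therapy_days,
       emergency_case = emergency_case, inpatient_need = inpatient_need,
       surgery_indication = surgery_indication,
       complicating_infection = complicating_infection,
       screening_error = screening_error,
       consent_withdrawn = consent_withdrawn)
}

baseline_rec <- function(age_years = 46, crp_mg_dl = 1.4,
                         endoscopic_score = 1, perianal_lesions = 0,
                         stenosis = 0, fistula = 0, eim = 0,
                         fever_gt38 = 0, patient_id = NULL) {
  b <- data.frame(age_years = age_years, crp_mg_dl = crp_mg_dl,
                  endoscopic_score = endoscopic_score,
                  perianal_lesions = perianal_lesions, stenosis = stenosis,
                  fistula = fistula, eim = eim, fever_gt38 = fever_gt38)
  if (!is.null(patient_id)) b <- cbind(patient_id = patient_id, b)
  b
}

tte_df <- function(time, event, risk = NULL) {
  df <- data.frame(time_months = time, event = event)
  if (!is.null(risk)) {
    df$risk_class <- factor(risk,
                            levels = c("mild_predicted", "severe_predicted"))
  }
  df
}

small_cohort <- function(seed = 11, n_low = 6, n_high = 8) {
  generate_cohort(cohort_config(n_low = n_low, n_high = n_high, seed = seed))
}
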