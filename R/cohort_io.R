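#' @title Cohort tables: screening, schemas, readers and writers
#' @description
#' The cohort is stored as four flat CSV tables keyed by `patient_id`:
#' `baseline.csv` (diagnosis-time covariates), `therapy.csv` (therapy
#' episodes in study days; an empty `stop_day` means ongoing), `events.csv`
#' (Crohn's-related surgery and IBD hospitalisation days) and `visits.csv`
#' (scheduled follow-up contacts; the maximum day per patient is the
#' censoring day). All timestamps are integer study days relative to the
#' baseline visit (day 0); calendar dates are not modelled.
#' @name cohort_io
NULL

.exclusion_rules <- c("diagnosis-window", "prior-therapy", "emergency",
                      "inpatient", "surgery", "infection", "screening-error",
                      "consent")

.permitted_prior <- c("mesalazine", "budesonide", "prednisolone")
.prior_kinds <- c("none", .permitted_prior, "other")

#' Screen one patient record against the study eligibility rules
#'
#' An inception-cohort patient is eligible when the Crohn's diagnosis was
#' made at most 42 days (six weeks, inclusive) before inclusion, any prior
#' therapy was a single short course of mesalazine or an oral steroid
#' (budesonide or prednisolone) of at most 10 days, and none of the
#' exclusion conditions apply (emergency requiring immediate intensified
#' therapy, need for inpatient treatment, clear surgical indication,
#' complicating infection), nor a screening error or withdrawn consent.
#' Rules are evaluated in a fixed order and the first failing rule names the
#' exclusion reason.
#'
#' @param rec A list or one-row data frame with fields
#'   `days_since_diagnosis`, `prior_therapy_kind` (one of `none`,
#'   `mesalazine`, `budesonide`, `prednisolone`, `other`),
#'   `prior_therapy_days`, and logical flags `emergency_case`,
#'   `inpatient_need`, `surgery_indication`, `complicating_infection`,
#'   `screening_error`, `consent_withdrawn`.
#' @return A list with `eligible` (logical) and `reason` (`NA` when
#'   eligible, otherwise one of the reason codes `diagnosis-window`,
#'   `prior-therapy`, `emergency`, `inpatient`, `surgery`, `infection`,
#'   `screening-error`, `consent`).
#' @export
screen_eligibility <- function(rec) {
  rec <- as.list(rec)
  .check_numeric(rec$days_since_diagnosis, "days_since_diagnosis",
                 min = 0, integer = TRUE)
  .check_numeric(rec$prior_therapy_days, "prior_therapy_days",
                 min = 0, integer = TRUE)
  if (!is.character(rec$prior_therapy_kind) ||
      !(rec$prior_therapy_kind %in% .prior_kinds)) {
    stop("prior_therapy_kind must be one of: ",
         paste(.prior_kinds, collapse = ", "), call. = FALSE)
  }
  for (nm in c("emergency_case", "inpatient_need", "surgery_indication",
               "complicating_infection", "screening_error",
               "consent_withdrawn")) {
    .check_flag(rec[[nm]], nm)
  }
  prior_ok <- rec$prior_therapy_kind == "none" ||
    (rec$prior_therapy_kind %in% .permitted_prior &&
       rec$prior_therapy_days <= 10)
  failing <- c(
    "diagnosis-window" = rec$days_since_diagnosis > 42,
    "prior-therapy"    = !prior_ok,
    "emergency"        = as.logical(rec$emergency_case),
    "inpatient"        = as.logical(rec$inpatient_need),
    "surgery"          = as.logical(rec$surgery_indication),
    "infection"        = as.logical(rec$complicating_infection),
    "screening-error"  = as.logical(rec$screening_error),
    "consent"          = as.logical(rec$consent_withdrawn)
  )
  if (any(failing)) {
    list(eligible = FALSE, reason = names(failing)[which(failing)[1]])
  } else {
    list(eligible = TRUE, reason = NA_character_)
  }
}

#' Tally the study flow from a screening table
#'
#' Counts patients passing the clinical eligibility rules
#' (diagnosis window, prior therapy, and the four exclusion conditions),
#' then removes screening errors and consent withdrawals among them; a
#' record flagged for both counts as a screening error only. The counts
#' always satisfy `final_cohort = screened_eligible - screening_errors -
#' withdrawals`.
#'
#' @param records A data frame of screening records (columns as in
#'   [screen_eligibility()], plus `patient_id`).
#' @return A list with `screened_eligible`, `screening_errors`,
#'   `withdrawals` and `final_cohort`.
#' @export
apply_flow <- function(records) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0) {
    return(list(screened_eligible = 0L, screening_errors = 0L,
                withdrawals = 0L, final_cohort = 0L))
  }
  records <- as.data.frame(records)
  verdicts <- lapply(seq_len(nrow(records)),
                     function(i) screen_eligibility(records[i, ]))
  reason <- vapply(verdicts, function(v) {
    if (v$eligible) "eligible" else v$reason
  }, character(1))
  # clinically eligible = passed the six clinical rules (reason is either
  # none, a screening error, or a consent withdrawal)
  clin <- reason %in% c("eligible", "screening-error", "consent")
  eligible <- sum(clin)
  errors <- sum(reason == "screening-error")
  withdrawals <- sum(reason == "consent")
  list(screened_eligible = as.integer(eligible),
       screening_errors = as.integer(errors),
       withdrawals = as.integer(withdrawals),
       final_cohort = as.integer(eligible - errors - withdrawals))
}

#' Read a screening table
#'
#' @param path Path to a screening CSV with the columns documented in
#'   [screen_eligibility()].
#' @return A data frame of screening records.
#' @export
read_screening <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "days_since_diagnosis", "prior_therapy_kind",
           "prior_therapy_days", "emergency_case", "inpatient_need",
           "surgery_indication", "complicating_infection", "screening_error",
           "consent_withdrawn")
  .check_columns(df, req, basename(path))
  df
}

# -- cohort container ---------------------------------------------------------

.baseline_cols <- c("patient_id", "age_years", "crp_mg_dl",
                    "endoscopic_score", "perianal_lesions", "stenosis",
                    "fistula", "eim", "fever_gt38")
.therapy_cols <- c("patient_id", "drug_class", "start_day", "stop_day")
.events_cols <- c("patient_id", "event_kind", "day")
.visits_cols <- c("patient_id", "day")

.drug_classes <- c("mesalazine", "budesonide", "systemic_steroid",
                   "immunosuppressant", "biologic", "other")
.event_kinds <- c("cd_surgery", "ibd_hospitalization")

#' Construct a cohort dataset from its four tables
#'
#' @param baseline,therapy,events,visits Data frames following the CSV
#'   schemas described in [cohort_io].
#' @param validate Run [validate_cohort()] on the result (default `TRUE`).
#' @return An object of class `premicc_cohort` (a list of the four tables).
#' @export
cohort_dataset <- function(baseline,
                           therapy = .empty_df(.therapy_cols),
                           events = .empty_df(.events_cols),
                           visits = .empty_df(.visits_cols),
                           validate = TRUE) {
  ds <- structure(list(baseline = as.data.frame(baseline),
                       therapy = as.data.frame(therapy),
                       events = as.data.frame(events),
                       visits = as.data.frame(visits)),
                  class = "premicc_cohort")
  if (validate) validate_cohort(ds)
  ds
}

.empty_df <- function(cols) {
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols))
  for (col in setdiff(cols, c("patient_id", "drug_class", "event_kind"))) {
    df[[col]] <- numeric(0)
  }
  df
}

#' Validate a cohort dataset against the table schemas
#'
#' Checks column presence, value ranges and enumerations, uniqueness of
#' baseline `patient_id`s, that every therapy/event/visit row refers to a
#' known patient, that every patient has at least one recorded visit, and
#' that no episode or event lies after the patient's last contact.
#' Violations raise an error naming the offending table and row.
#'
#' @param dataset A `premicc_cohort`.
#' @return The dataset, invisibly, when valid.
#' @export
validate_cohort <- function(dataset) {
  b <- dataset$baseline
  .check_columns(b, .baseline_cols, "baseline")
  .check_columns(dataset$therapy, .therapy_cols, "therapy")
  .check_columns(dataset$events, .events_cols, "events")
  .check_columns(dataset$visits, .visits_cols, "visits")

  if (anyDuplicated(b$patient_id)) {
    stop("baseline: duplicate patient_id '",
         b$patient_id[anyDuplicated(b$patient_id)], "'", call. = FALSE)
  }
  .check_rows(b, "baseline", function(r) {
    if (r$age_years < 0) return("negative age_years")
    if (r$crp_mg_dl < 0) return("negative crp_mg_dl")
    if (!(r$endoscopic_score %in% 0:4)) return("endoscopic_score not in 0..4")
    for (f in c("perianal_lesions", "stenosis", "fistula", "eim",
                "fever_gt38")) {
      if (!(r[[f]] %in% c(0, 1))) return(paste(f, "not 0/1"))
    }
    NULL
  })
  known <- b$patient_id
  last_contact <- .last_contact_days(dataset)

  if (nrow(b) > 0 && !all(known %in% dataset$visits$patient_id)) {
    missing <- setdiff(known, dataset$visits$patient_id)
    stop("visits: no visit recorded for patient '", missing[1], "'",
         call. = FALSE)
  }
  .check_rows(dataset$visits, "visits", function(r) {
    if (!(r$patient_id %in% known)) return("unknown patient_id")
    if (r$day < 0 || r$day != floor(r$day)) return("day must be a non-negative integer")
    NULL
  })
  .check_rows(dataset$therapy, "therapy", function(r) {
    if (!(r$patient_id %in% known)) return("unknown patient_id")
    if (!(r$drug_class %in% .drug_classes)) return("unknown drug_class")
    if (r$start_day < 0) return("negative start_day")
    if (!is.na(r$stop_day) && r$stop_day < r$start_day) {
      return("stop_day before start_day")
    }
    if (r$start_day > last_contact[[r$patient_id]]) {
      return("episode starts after last contact")
    }
    NULL
  })
  .check_rows(dataset$events, "events", function(r) {
    if (!(r$patient_id %in% known)) return("unknown patient_id")
    if (!(r$event_kind %in% .event_kinds)) return("unknown event_kind")
    if (r$day < 0) return("negative day")
    if (r$day > last_contact[[r$patient_id]]) {
      return("event after last contact")
    }
    NULL
  })
  invisible(dataset)
}

.last_contact_days <- function(dataset) {
  v <- dataset$visits
  if (nrow(v) == 0) return(list())
  tapply(v$day, v$patient_id, max, simplify = FALSE)
}

.check_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    stop(file, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

.check_rows <- function(df, file, fn) {
  for (i in seq_len(nrow(df))) {
    msg <- fn(as.list(df[i, ]))
    if (!is.null(msg)) {
      stop(file, " row ", i, ": ", msg, call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a cohort dataset from a directory of CSV files
#'
#' Expects `baseline.csv`, `therapy.csv`, `events.csv` and `visits.csv` in
#' `dir` (the latter three may have zero data rows). Reading a directory
#' written by [write_cohort()] reproduces the dataset field for field.
#'
#' @param dir Directory containing the four CSV tables.
#' @return A validated `premicc_cohort`.
#' @export
read_cohort <- function(dir) {
  read1 <- function(name, cols, classes) {
    path <- file.path(dir, name)
    if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = classes)
    .check_columns(df, cols, name)
    df[cols]
  }
  chr <- "character"; num <- "numeric"; int <- "integer"
  classes <- list(
    baseline = c(patient_id = chr, age_years = int, crp_mg_dl = num,
                 endoscopic_score = int, perianal_lesions = int,
                 stenosis = int, fistula = int, eim = int, fever_gt38 = int),
    therapy = c(patient_id = chr, drug_class = chr, start_day = num,
                stop_day = num),
    events = c(patient_id = chr, event_kind = chr, day = num),
    visits = c(patient_id = chr, day = int))
  cohort_dataset(
    baseline = read1("baseline.csv", .baseline_cols, classes$baseline),
    therapy = read1("therapy.csv", .therapy_cols, classes$therapy),
    events = read1("events.csv", .events_cols, classes$events),
    visits = read1("visits.csv", .visits_cols, classes$visits))
}

#' Write a cohort dataset to a directory of CSV files
#'
#' Writes the four schema tables; when the dataset carries a generator
#' configuration attribute (see [generate_cohort()]) a `metadata.json` with
#' the configuration and seed is written alongside.
#'
#' @param dataset A `premicc_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(dataset, dir) {
  validate_cohort(dataset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$baseline, file.path(dir, "baseline.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$therapy, file.path(dir, "therapy.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$visits, file.path(dir, "visits.csv"),
                   row.names = FALSE)
  cfg <- attr(dataset, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(cfg, file.path(dir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @export
print.premicc_cohort <- function(x, ...) {
  cat("premicc cohort: ", nrow(x$baseline), " patients, ",
      nrow(x$therapy), " therapy episodes, ", nrow(x$events),
      " clinical events, ", nrow(x$visits), " visits\n", sep = "")
  invisible(x)
}
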