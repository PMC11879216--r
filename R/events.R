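#' @title Treatment-escalation events and time-to-event records
#' @description
#' Turns a patient's longitudinal timeline into the study's two outcome
#' constructs. (1) The week-8 escalation flag: by the week-8 visit (day 56)
#' the patient received therapy other than mesalazine, was not steroid-free
#' for the two weeks before the visit (days 43-56), started an
#' immunosuppressant or biologic, or underwent Crohn's-related surgery.
#' (2) The time-to-first-outcome-failure record, where a failure is a
#' steroid or budesonide escalation beyond induction, the initiation of
#' immunosuppressive or biologic therapy at any time, or an IBD-related
#' hospitalisation or surgery. Induction steroids that start within the
#' first 8 weeks and end before day 43 are treated as part of initial
#' therapy and do not count as failures.
#' @name events
NULL

.steroid_classes <- c("budesonide", "systemic_steroid")
.immuno_classes <- c("immunosuppressant", "biologic")

#' Event-definition configuration
#'
#' @param week8_day Day of the week-8 escalation assessment (default 56).
#' @param steroid_window_start_day First day of the pre-assessment
#'   steroid-free window (default 43: "steroid-free for 2 weeks").
#' @param days_per_month Fixed month length used for all day-to-month
#'   conversions (default 30.4375 days).
#' @param zero_time_months Positive time substituted for day-0 events so
#'   product-limit code never sees t = 0 (default 1e-6 months).
#' @return A list of class `premicc_event_config`.
#' @export
event_config <- function(week8_day = 56L, steroid_window_start_day = 43L,
                         days_per_month = 30.4375,
                         zero_time_months = 1e-6) {
  stopifnot(week8_day > 0, steroid_window_start_day > 0,
            steroid_window_start_day <= week8_day,
            days_per_month > 0, zero_time_months > 0)
  structure(list(week8_day = week8_day,
                 steroid_window_start_day = steroid_window_start_day,
                 days_per_month = days_per_month,
                 zero_time_months = zero_time_months),
            class = "premicc_event_config")
}

#' Build one patient's follow-up timeline
#'
#' @param patient_id Patient identifier.
#' @param episodes Data frame with `drug_class`, `start_day`, `stop_day`
#'   (`NA` = ongoing; ongoing episodes truncate at last contact).
#' @param events Data frame with `event_kind`
#'   (`cd_surgery`/`ibd_hospitalization`) and `day`.
#' @param last_contact_day Final contact day (censoring day).
#' @return An object of class `followup_timeline`.
#' @export
followup_timeline <- function(patient_id, episodes = NULL, events = NULL,
                              last_contact_day) {
  if (is.null(episodes) || nrow(episodes) == 0) {
    episodes <- data.frame(drug_class = character(0), start_day = numeric(0),
                           stop_day = numeric(0))
  }
  if (is.null(events) || nrow(events) == 0) {
    events <- data.frame(event_kind = character(0), day = numeric(0))
  }
  .check_numeric(last_contact_day, "last_contact_day", min = 0,
                 integer = TRUE)
  if (nrow(episodes) > 0) {
    if (!all(episodes$drug_class %in% .drug_classes)) {
      stop("unknown drug_class in episodes", call. = FALSE)
    }
    if (any(episodes$start_day < 0) ||
        any(!is.na(episodes$stop_day) &
              episodes$stop_day < episodes$start_day)) {
      stop("episode days must satisfy 0 <= start_day <= stop_day",
           call. = FALSE)
    }
    if (any(episodes$start_day > last_contact_day)) {
      stop("episode starts after last contact for patient ", patient_id,
           call. = FALSE)
    }
  }
  if (nrow(events) > 0) {
    if (!all(events$event_kind %in% .event_kinds)) {
      stop("unknown event_kind", call. = FALSE)
    }
    if (any(events$day < 0) || any(events$day > last_contact_day)) {
      stop("event day outside [0, last_contact_day] for patient ",
           patient_id, call. = FALSE)
    }
  }
  structure(list(patient_id = as.character(patient_id),
                 episodes = episodes, events = events,
                 last_contact_day = as.integer(last_contact_day)),
            class = "followup_timeline")
}

#' Split a cohort dataset into per-patient timelines
#'
#' @param dataset A validated `premicc_cohort`.
#' @return A named list of `followup_timeline` objects, ordered by
#'   `patient_id`.
#' @export
cohort_timelines <- function(dataset) {
  ids <- sort(unique(as.character(dataset$baseline$patient_id)))
  last <- .last_contact_days(dataset)
  out <- lapply(ids, function(id) {
    ep <- dataset$therapy[dataset$therapy$patient_id == id,
                          c("drug_class", "start_day", "stop_day")]
    ev <- dataset$events[dataset$events$patient_id == id,
                         c("event_kind", "day")]
    followup_timeline(id, ep, ev, last[[id]])
  })
  stats::setNames(out, ids)
}

#' Week-8 escalation assessment
#'
#' Returns `TRUE` when any of the four escalation criteria fires within the
#' first 56 days: (1) therapy other than mesalazine (a drug class outside
#' mesalazine, steroids and immunomodulators/biologics, i.e. `other`);
#' (2) steroid exposure (budesonide or systemic steroid) overlapping the
#' steroid-free window, days 43-56; (3) an immunosuppressant or biologic
#' episode starting on or before day 56; (4) Crohn's-related surgery on or
#' before day 56. Episodes entirely after day 56 never affect the flag.
#'
#' @param timeline A `followup_timeline`.
#' @param cfg An [event_config()].
#' @return Logical scalar.
#' @export
assess_week8_escalation <- function(timeline, cfg = event_config()) {
  ep <- timeline$episodes
  w8 <- cfg$week8_day
  if (nrow(ep) > 0) {
    stop_eff <- ifelse(is.na(ep$stop_day), timeline$last_contact_day,
                       ep$stop_day)
    steroid <- ep$drug_class %in% .steroid_classes
    if (any(ep$drug_class == "other" & ep$start_day <= w8)) return(TRUE)
    if (any(steroid & ep$start_day <= w8 &
              stop_eff >= cfg$steroid_window_start_day)) return(TRUE)
    if (any(ep$drug_class %in% .immuno_classes & ep$start_day <= w8)) {
      return(TRUE)
    }
  }
  ev <- timeline$events
  nrow(ev) > 0 && any(ev$event_kind == "cd_surgery" & ev$day <= w8)
}

#' Derive the time-to-first-outcome-failure record for one patient
#'
#' Failure days are: the start of any steroid or budesonide episode
#' beginning after day 56 (escalation beyond induction); the first day
#' inside the steroid-free window (days 43-56) of any steroid exposure
#' overlapping it; the start of any immunosuppressant or biologic episode;
#' and the day of any Crohn's-related surgery or IBD hospitalisation. The
#' record carries the earliest failure day converted to months (divisor
#' 30.4375 days/month); with no failure the patient is censored at last
#' contact. Day-0 failures are clamped to a small positive time.
#'
#' @param timeline A `followup_timeline`.
#' @param cfg An [event_config()].
#' @return One-row data frame: `patient_id`, `time_months`, `event`
#'   (logical), `failure_kind` (`steroid`, `immunomodulator_biologic`,
#'   `surgery`, `hospitalization`, or `NA` when censored).
#' @export
derive_failure <- function(timeline, cfg = event_config()) {
  ep <- timeline$episodes
  days <- numeric(0)
  kinds <- character(0)
  if (nrow(ep) > 0) {
    stop_eff <- ifelse(is.na(ep$stop_day), timeline$last_contact_day,
                       ep$stop_day)
    steroid <- ep$drug_class %in% .steroid_classes
    late <- steroid & ep$start_day > cfg$week8_day
    days <- c(days, ep$start_day[late])
    kinds <- c(kinds, rep("steroid", sum(late)))
    overl <- steroid & ep$start_day <= cfg$week8_day &
      stop_eff >= cfg$steroid_window_start_day
    days <- c(days, pmax(ep$start_day[overl], cfg$steroid_window_start_day))
    kinds <- c(kinds, rep("steroid", sum(overl)))
    im <- ep$drug_class %in% .immuno_classes
    days <- c(days, ep$start_day[im])
    kinds <- c(kinds, rep("immunomodulator_biologic", sum(im)))
  }
  ev <- timeline$events
  if (nrow(ev) > 0) {
    days <- c(days, ev$day)
    kinds <- c(kinds, ifelse(ev$event_kind == "cd_surgery", "surgery",
                             "hospitalization"))
  }
  if (length(days) > 0) {
    d <- min(days)
    if (d > timeline$last_contact_day) {
      stop("failure day ", d, " after last contact for patient ",
           timeline$patient_id, call. = FALSE)
    }
    tm <- if (d == 0) cfg$zero_time_months else d / cfg$days_per_month
    kind_order <- c("steroid", "immunomodulator_biologic", "surgery",
                    "hospitalization")
    at_min <- kinds[days == d]
    kind <- kind_order[min(match(at_min, kind_order))]
    data.frame(patient_id = timeline$patient_id, time_months = tm,
               event = TRUE, failure_kind = kind, stringsAsFactors = FALSE)
  } else {
    d <- timeline$last_contact_day
    tm <- if (d == 0) cfg$zero_time_months else d / cfg$days_per_month
    data.frame(patient_id = timeline$patient_id, time_months = tm,
               event = FALSE, failure_kind = NA_character_,
               stringsAsFactors = FALSE)
  }
}

#' Build the cohort time-to-event dataset
#'
#' Derives one time-to-first-failure record per patient and joins the
#' predicted risk class from the scoring results. Records are ordered by
#' `patient_id`.
#'
#' @param dataset A `premicc_cohort`.
#' @param scores Scoring results from [compute_score()] (must contain
#'   `patient_id` and `risk_class` covering every patient).
#' @param cfg An [event_config()].
#' @return Data frame with `patient_id`, `time_months`, `event`,
#'   `failure_kind`, `risk_class`.
#' @export
build_tte_dataset <- function(dataset, scores, cfg = event_config()) {
  tl <- cohort_timelines(dataset)
  if (length(tl) == 0) {
    return(data.frame(patient_id = character(0), time_months = numeric(0),
                      event = logical(0), failure_kind = character(0),
                      risk_class = factor(character(0),
                                          levels = .risk_levels)))
  }
  recs <- do.call(rbind, lapply(tl, derive_failure, cfg = cfg))
  idx <- match(recs$patient_id, as.character(scores$patient_id))
  if (anyNA(idx)) {
    stop("no score for patient '", recs$patient_id[which(is.na(idx))[1]],
         "'", call. = FALSE)
  }
  recs$risk_class <- scores$risk_class[idx]
  rownames(recs) <- NULL
  recs[order(recs$patient_id), , drop = FALSE]
}
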