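#' @title Synthetic inception-cohort generator
#' @description
#' Generates cohorts with the statistical structure the validation assumes:
#' two score strata whose covariates are drawn to match the study's
#' baseline marginals (low stratum: median age 46 y, median CRP 1.4 mg/dL,
#' endoscopy mostly grade <= 1, rare flags; high stratum: median age 29 y,
#' median CRP 14.4 mg/dL, endoscopy mostly grade > 1, flags per the
#' high-score column), stratum-specific front-loaded piecewise-exponential
#' escalation hazards, and censoring snapped to the scheduled visit grid
#' (every 3 months in year one, every 6 months to year three, then
#' annually). Rejection sampling guarantees every generated record scores
#' into its intended stratum, so the scoring round-trip recovers the strata
#' exactly.
#' @name synthetic_data
NULL

#' Piecewise-constant hazard on the month scale
#'
#' Rates apply to the intervals partitioning `[0, Inf)` delimited by the
#' breakpoints, so `rates` has one more element than `breakpoints`.
#'
#' @param breakpoints Ascending positive breakpoints (months); may be empty
#'   for a constant hazard.
#' @param rates Nonnegative per-month hazard rates, one per interval.
#' @return An object of class `piecewise_hazard`.
#' @examples
#' piecewise_hazard(6, c(0.13, 0.014))   # front-loaded
#' piecewise_hazard(numeric(0), 0.0339)  # constant
#' @export
piecewise_hazard <- function(breakpoints, rates) {
  breakpoints <- as.numeric(breakpoints)
  rates <- as.numeric(rates)
  if (length(rates) != length(breakpoints) + 1) {
    stop("need one rate per interval: length(rates) == length(breakpoints) + 1",
         call. = FALSE)
  }
  if (length(breakpoints) > 0 &&
      (any(breakpoints <= 0) || is.unsorted(breakpoints, strictly = TRUE))) {
    stop("breakpoints must be positive and strictly increasing",
         call. = FALSE)
  }
  if (any(rates < 0) || anyNA(rates)) {
    stop("rates must be nonnegative", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, rates = rates),
            class = "piecewise_hazard")
}

# Calibration: cumulative hazard over 36 months reproduces the study's
# stratum escalation proportions (24.2% low, 70.2% high), with an early
# segment (months 0-6) carrying most of the hazard so that most events
# fall within the first 6 months.
.default_hazard_low <- function() {
  h36 <- -log(1 - 0.242)
  r1 <- 0.03
  piecewise_hazard(6, c(r1, (h36 - 6 * r1) / 30))
}

.default_hazard_high <- function() {
  h36 <- -log(1 - 0.702)
  r1 <- 0.13
  piecewise_hazard(6, c(r1, (h36 - 6 * r1) / 30))
}

#' Cohort generator configuration
#'
#' Defaults are the validation study's conditions: strata of 88 (score
#' <= 2) and 113 (score > 2) patients, front-loaded escalation hazards
#' calibrated so the cumulative escalation probability at month 36 is
#' 24.2% (low stratum) and 70.2% (high stratum), administrative censoring
#' at month 60 with a small monthly dropout rate, and the study's visit
#' schedule.
#'
#' @param n_low,n_high Stratum sizes (score <= 2 / score > 2).
#' @param hazard_low,hazard_high [piecewise_hazard()] objects for
#'   time-to-escalation in each stratum.
#' @param administrative_month End of observation (months).
#' @param dropout_rate_per_month Exponential dropout rate (per month).
#' @param visit_schedule Strictly increasing visit months starting at 0.
#' @param realization Named probability weights over how a planned failure
#'   is written into the timeline: `biologic`, `immunosuppressant`,
#'   `steroid`, `cd_surgery`, `ibd_hospitalization`. A `steroid`
#'   realization of a failure planned on or before day 56 falls back to a
#'   biologic episode so the planned day stays recoverable.
#' @param seed Integer seed; recorded in the output metadata.
#' @return A list of class `premicc_cohort_config`.
#' @export
cohort_config <- function(n_low = 88L, n_high = 113L,
                          hazard_low = .default_hazard_low(),
                          hazard_high = .default_hazard_high(),
                          administrative_month = 60,
                          dropout_rate_per_month = 0.004,
                          visit_schedule = c(0, 3, 6, 9, 12, 18, 24, 30,
                                             36, 48, 60),
                          realization = c(biologic = 1),
                          seed = 1L) {
  stopifnot(n_low >= 0, n_high >= 0,
            inherits(hazard_low, "piecewise_hazard"),
            inherits(hazard_high, "piecewise_hazard"),
            administrative_month > 0, dropout_rate_per_month >= 0,
            length(visit_schedule) >= 1, visit_schedule[1] == 0,
            !is.unsorted(visit_schedule, strictly = TRUE),
            all(names(realization) %in%
                  c("biologic", "immunosuppressant", "steroid",
                    "cd_surgery", "ibd_hospitalization")),
            all(realization >= 0), sum(realization) > 0)
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high),
                 hazard_low = hazard_low, hazard_high = hazard_high,
                 administrative_month = administrative_month,
                 dropout_rate_per_month = dropout_rate_per_month,
                 visit_schedule = visit_schedule,
                 realization = realization / sum(realization),
                 seed = as.integer(seed)),
            class = "premicc_cohort_config")
}

#' Single-arm configuration for the pooled-course scenario
#'
#' The pooled 36-month mild-course proportion (29.5%) and the stratified
#' escalation proportions cannot both hold in one cohort, so the pooled
#' figure gets its own single-arm scenario: one stratum of 201 patients
#' with a constant hazard of `-log(0.295)/36` per month.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `premicc_cohort_config` with `n_low = 0`.
#' @export
cohort_config_pooled <- function(n = 201L, seed = 1L, ...) {
  rate <- -log(0.295) / 36
  cohort_config(n_low = 0L, n_high = n,
                hazard_high = piecewise_hazard(numeric(0), rate),
                seed = seed, ...)
}

# stratum covariate samplers; marginals follow the study's baseline table
.draw_low <- function(n) {
  data.frame(
    age_years = pmax(16L, as.integer(round(exp(stats::rnorm(n, log(46), 0.35))))),
    crp_mg_dl = round(exp(stats::rnorm(n, log(1.4), 0.9)), 1),
    endoscopic_score = sample(0:4, n, replace = TRUE,
                              prob = c(0.034, 0.591, 0.261, 0.102, 0.011)),
    perianal_lesions = as.integer(stats::runif(n) < 0.011),
    stenosis = as.integer(stats::runif(n) < 0.011),
    fistula = integer(n), eim = integer(n), fever_gt38 = integer(n))
}

.draw_high <- function(n) {
  data.frame(
    age_years = pmax(16L, as.integer(round(exp(stats::rnorm(n, log(29), 0.35))))),
    crp_mg_dl = round(exp(stats::rnorm(n, log(14.4), 1.0)), 1),
    endoscopic_score = sample(0:4, n, replace = TRUE,
                              prob = c(0.009, 0.159, 0.345, 0.283, 0.204)),
    perianal_lesions = as.integer(stats::runif(n) < 0.088),
    stenosis = as.integer(stats::runif(n) < 0.177),
    fistula = as.integer(stats::runif(n) < 0.053),
    eim = as.integer(stats::runif(n) < 0.062),
    fever_gt38 = as.integer(stats::runif(n) < 0.018))
}

.gen_stratum <- function(n, draw, want_mild, max_rounds = 1000) {
  if (n == 0) return(draw(0))
  out <- draw(0)
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(out)
    if (need == 0) break
    cand <- draw(need)
    sc <- compute_score(cand)
    keep <- if (want_mild) sc$total <= 2 else sc$total > 2
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  if (nrow(out) < n) {
    stop("could not realize the requested score stratum after ",
         max_rounds, " resampling rounds", call. = FALSE)
  }
  out[seq_len(n), , drop = FALSE]
}

.gen_baseline <- function(cfg) {
  low <- .gen_stratum(cfg$n_low, .draw_low, want_mild = TRUE)
  high <- .gen_stratum(cfg$n_high, .draw_high, want_mild = FALSE)
  b <- rbind(low, high)
  n <- nrow(b)
  b <- cbind(patient_id = sprintf("P%04d", seq_len(n)), b,
             stringsAsFactors = FALSE)
  rownames(b) <- NULL
  b
}

#' Generate stratified baseline records
#'
#' Draws `n_low` records that score 2 or less and `n_high` records that
#' score above 2 (rejection resampling enforces the stratum), seeded from
#' `cfg$seed`.
#'
#' @param cfg A [cohort_config()].
#' @return A baseline data frame (see [cohort_io] schema), low stratum
#'   first.
#' @export
generate_baseline <- function(cfg) {
  set.seed(cfg$seed)
  .gen_baseline(cfg)
}

#' Sample event times from a piecewise-exponential distribution
#'
#' Inverse-CDF sampling: a uniform draw u is mapped through the inverse
#' cumulative hazard, t = H^{-1}(-log u). Intervals with zero rate
#' contribute nothing; when the total cumulative hazard is exhausted the
#' event never occurs and `Inf` is returned.
#'
#' @param n Number of draws.
#' @param h A [piecewise_hazard()].
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return Numeric vector of positive event times in months (possibly
#'   `Inf`).
#' @export
sample_event_times <- function(n, h, seed = NULL) {
  if (!inherits(h, "piecewise_hazard")) {
    stop("h must be a piecewise_hazard", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  starts <- c(0, h$breakpoints)
  widths <- c(diff(starts), Inf)
  inc <- h$rates * widths
  inc[is.nan(inc)] <- 0          # 0 * Inf on a zero-rate tail
  h_start <- cumsum(c(0, inc))[seq_along(h$rates)]
  target <- -log(stats::runif(n))
  idx <- findInterval(target, h_start)
  t <- starts[idx] + (target - h_start[idx]) / h$rates[idx]
  t[h$rates[idx] == 0] <- Inf
  t
}

#' Realize planned event times as follow-up timelines
#'
#' Every patient gets a background mesalazine episode from day 0. A finite
#' planned event time that precedes censoring is written into the timeline
#' as a failure the event classifier can recover exactly on the planned day
#' (by default a biologic episode starting that day; the `realization` mix
#' in the config allows steroid, surgery or hospitalisation realizations).
#' The censoring day is the minimum of administrative censoring and
#' exponential dropout, snapped up to the next scheduled visit and capped
#' at the administrative month; planned events falling after it are dropped
#' (the patient is censored) and counted in the `n_dropped_events`
#' attribute.
#'
#' @param baseline Baseline data frame (defines patient order).
#' @param event_months Numeric vector of planned event times (months,
#'   `Inf` = no event), aligned with `baseline` rows.
#' @param cfg A [cohort_config()].
#' @param cfg_events An [event_config()] (for the day/month conversion).
#' @return A named list of `followup_timeline` objects with attribute
#'   `n_dropped_events`.
#' @export
realize_timelines <- function(baseline, event_months, cfg,
                              cfg_events = event_config()) {
  stopifnot(nrow(baseline) == length(event_months))
  dpm <- cfg_events$days_per_month
  vs <- cfg$visit_schedule
  n <- nrow(baseline)
  dropped <- 0L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    dropout_m <- if (cfg$dropout_rate_per_month > 0) {
      stats::rexp(1, cfg$dropout_rate_per_month)
    } else Inf
    raw_cens <- min(cfg$administrative_month, dropout_m)
    later <- vs[vs >= raw_cens]
    cens_m <- min(if (length(later) > 0) min(later) else
      cfg$administrative_month, cfg$administrative_month)
    cens_day <- as.integer(round(cens_m * dpm))
    episodes <- data.frame(drug_class = "mesalazine", start_day = 0,
                           stop_day = NA_real_, stringsAsFactors = FALSE)
    events <- NULL
    ev_m <- event_months[i]
    if (is.finite(ev_m)) {
      ev_day <- max(1L, as.integer(round(ev_m * dpm)))
      if (ev_day <= cens_day) {
        kind <- sample(names(cfg$realization), 1, prob = cfg$realization)
        if (kind == "steroid" && ev_day <= cfg_events$week8_day) {
          kind <- "biologic"
        }
        if (kind %in% c("cd_surgery", "ibd_hospitalization")) {
          events <- data.frame(event_kind = kind, day = ev_day,
                               stringsAsFactors = FALSE)
        } else {
          drug <- if (kind == "steroid") "systemic_steroid" else kind
          episodes <- rbind(episodes,
                            data.frame(drug_class = drug, start_day = ev_day,
                                       stop_day = NA_real_,
                                       stringsAsFactors = FALSE))
        }
      } else {
        dropped <- dropped + 1L
      }
    }
    out[[i]] <- followup_timeline(baseline$patient_id[i], episodes, events,
                                  cens_day)
  }
  names(out) <- baseline$patient_id
  attr(out, "n_dropped_events") <- dropped
  out
}

.visit_rows <- function(timeline, cfg, dpm) {
  days <- as.integer(round(cfg$visit_schedule * dpm))
  days <- unique(c(days[days <= timeline$last_contact_day],
                   timeline$last_contact_day))
  data.frame(patient_id = timeline$patient_id, day = sort(days),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Composes [generate_baseline()], [sample_event_times()] per stratum and
#' [realize_timelines()] into a schema-valid cohort dataset. The generator
#' configuration (including the seed) is attached as the `config`
#' attribute and written as `metadata.json` by [write_cohort()]. Identical
#' configuration and seed give identical datasets.
#'
#' @param cfg A [cohort_config()].
#' @param cfg_events An [event_config()].
#' @return A validated `premicc_cohort`.
#' @export
generate_cohort <- function(cfg = cohort_config(),
                            cfg_events = event_config()) {
  set.seed(cfg$seed)
  baseline <- .gen_baseline(cfg)
  ev <- c(sample_event_times(cfg$n_low, cfg$hazard_low),
          sample_event_times(cfg$n_high, cfg$hazard_high))
  tls <- realize_timelines(baseline, ev, cfg, cfg_events)
  dpm <- cfg_events$days_per_month
  therapy <- do.call(rbind, lapply(tls, function(tl) {
    if (nrow(tl$episodes) == 0) return(NULL)
    cbind(patient_id = tl$patient_id, tl$episodes, stringsAsFactors = FALSE)
  }))
  events <- do.call(rbind, lapply(tls, function(tl) {
    if (nrow(tl$events) == 0) return(NULL)
    cbind(patient_id = tl$patient_id, tl$events, stringsAsFactors = FALSE)
  }))
  visits <- do.call(rbind, lapply(tls, .visit_rows, cfg = cfg, dpm = dpm))
  if (is.null(therapy)) therapy <- .empty_df(.therapy_cols)
  if (is.null(events)) events <- .empty_df(.events_cols)
  if (is.null(visits)) visits <- .empty_df(.visits_cols)
  rownames(therapy) <- rownames(events) <- rownames(visits) <- NULL
  ds <- cohort_dataset(baseline, therapy[.therapy_cols],
                       events[.events_cols], visits[.visits_cols])
  meta <- list(
    n_low = cfg$n_low, n_high = cfg$n_high,
    hazard_low = unclass(cfg$hazard_low),
    hazard_high = unclass(cfg$hazard_high),
    administrative_month = cfg$administrative_month,
    dropout_rate_per_month = cfg$dropout_rate_per_month,
    visit_schedule = cfg$visit_schedule,
    realization = as.list(cfg$realization),
    seed = cfg$seed,
    n_dropped_events = attr(tls, "n_dropped_events"))
  attr(ds, "config") <- meta
  ds
}
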