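#' @title PreMiCC scoring engine
#' @description
#' The PreMiCC ("prediction score for a mild course of Crohn's disease") is a
#' 0-6 point sum over five baseline parameters measured at first diagnosis:
#' age (1 point if <= 40 years), C-reactive protein in mg/dL (0 points below
#' 2, 1 point in the closed band \[2, 4\], 2 points above 4), endoscopic
#' severity in the worst bowel segment on a 0-4 ordinal scale (1 point above
#' 1), perianal lesions (1 point), and the presence of at least one
#' complication among stenosis, any fistula, extraintestinal manifestation or
#' fever above 38 degrees C (1 point). A total of 2 points or fewer predicts
#' a mild (nonprogressive) disease course.
#' @name scoring
NULL

.risk_levels <- c("mild_predicted", "severe_predicted")

#' Age component of the PreMiCC score
#'
#' @param age_years Integer vector of ages at first diagnosis, in years.
#' @return Integer vector of points: 1 for age <= 40, else 0.
#' @examples
#' score_age(c(29, 40, 46))
#' @export
score_age <- function(age_years) {
  .check_numeric(age_years, "age_years", min = 0)
  as.integer(age_years <= 40)
}

#' C-reactive protein component of the PreMiCC score
#'
#' CRP is banded at 2 and 4 mg/dL. The middle band is the closed interval
#' \[2, 4\] so the three bands partition the nonnegative axis: 2.0 and 4.0
#' both score 1 point.
#'
#' @param crp_mg_dl Numeric vector of CRP values, mg/dL.
#' @return Integer vector of points in 0..2.
#' @examples
#' score_crp(c(1.4, 3.0, 14.4))
#' @export
score_crp <- function(crp_mg_dl) {
  .check_numeric(crp_mg_dl, "crp_mg_dl", min = 0)
  as.integer(ifelse(crp_mg_dl < 2, 0L, ifelse(crp_mg_dl <= 4, 1L, 2L)))
}

#' Endoscopy component of the PreMiCC score
#'
#' The input is the already-reduced ordinal severity of the bowel segment
#' with the most severe lesions: 0 no lesions; 1 a few aphthous lesions or
#' fewer than five small ulcerations; 2 aphthous lesions and more than five
#' ulcerations with areas of normal mucosa; 3 diffuse mucosal inflammation
#' with aphthous lesions and ulcerations; 4 diffuse large ulcerations and/or
#' stenosis.
#'
#' @param endoscopic_score Integer vector with values in 0..4.
#' @return Integer vector of points: 1 for scores above 1, else 0.
#' @export
score_endoscopy <- function(endoscopic_score) {
  .check_numeric(endoscopic_score, "endoscopic_score", min = 0, max = 4,
                 integer = TRUE)
  as.integer(endoscopic_score > 1)
}

#' Perianal and complication components of the PreMiCC score
#'
#' @param perianal Logical (or 0/1) vector: perianal lesions present.
#' @param stenosis,fistula,eim,fever Logical (or 0/1) vectors for the four
#'   complication flags (stenosis, any type of fistula, extraintestinal
#'   manifestation, fever > 38 C). One point if at least one is present.
#' @return A list with integer vectors `perianal_points` and
#'   `complication_points`.
#' @export
score_flags <- function(perianal, stenosis, fistula, eim, fever) {
  for (nm in c("perianal", "stenosis", "fistula", "eim", "fever")) {
    .check_flag(get(nm), nm)
  }
  list(
    perianal_points = as.integer(as.logical(perianal)),
    complication_points = as.integer(
      as.logical(stenosis) | as.logical(fistula) |
        as.logical(eim) | as.logical(fever))
  )
}

#' Classify a PreMiCC total into a predicted risk class
#'
#' @param total Integer vector of totals in 0..6.
#' @return Factor with levels `mild_predicted` (total <= 2) and
#'   `severe_predicted` (total > 2).
#' @export
classify_risk <- function(total) {
  .check_numeric(total, "total", min = 0, max = 6, integer = TRUE)
  factor(ifelse(total <= 2, .risk_levels[1], .risk_levels[2]),
         levels = .risk_levels)
}

#' Compute the PreMiCC score for baseline records
#'
#' Applies the five component rules to each row of a baseline table and sums
#' them. The returned per-patient total always lies in 0..6 and the risk
#' class is `mild_predicted` exactly when the total is 2 or less.
#'
#' @param baseline A data frame with columns `age_years`, `crp_mg_dl`,
#'   `endoscopic_score`, `perianal_lesions`, `stenosis`, `fistula`, `eim`,
#'   `fever_gt38` (and optionally `patient_id`, which is carried through).
#' @return A data frame with one row per input row: `patient_id` (if
#'   supplied), the five component point columns, `total` and `risk_class`.
#' @examples
#' b <- data.frame(age_years = 29, crp_mg_dl = 14.4, endoscopic_score = 3,
#'                 perianal_lesions = 0, stenosis = 0, fistula = 0,
#'                 eim = 0, fever_gt38 = 0)
#' compute_score(b)
#' @export
compute_score <- function(baseline) {
  req <- c("age_years", "crp_mg_dl", "endoscopic_score", "perianal_lesions",
           "stenosis", "fistula", "eim", "fever_gt38")
  miss <- setdiff(req, names(baseline))
  if (length(miss) > 0) {
    stop("baseline record is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(baseline[req])) {
    bad <- req[vapply(baseline[req], anyNA, logical(1))]
    stop("baseline record has missing values in: ",
         paste(bad, collapse = ", "), " (covariates are not imputed)",
         call. = FALSE)
  }
  fl <- score_flags(baseline$perianal_lesions, baseline$stenosis,
                    baseline$fistula, baseline$eim, baseline$fever_gt38)
  out <- data.frame(
    age_points = score_age(baseline$age_years),
    crp_points = score_crp(baseline$crp_mg_dl),
    endoscopy_points = score_endoscopy(baseline$endoscopic_score),
    perianal_points = fl$perianal_points,
    complication_points = fl$complication_points,
    stringsAsFactors = FALSE
  )
  out$total <- out$age_points + out$crp_points + out$endoscopy_points +
    out$perianal_points + out$complication_points
  out$risk_class <- classify_risk(out$total)
  if ("patient_id" %in% names(baseline)) {
    out <- cbind(patient_id = as.character(baseline$patient_id), out,
                 stringsAsFactors = FALSE)
  }
  out
}

# -- validation helpers -------------------------------------------------------

.check_numeric <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    stop(name, " must be numeric and non-missing", call. = FALSE)
  }
  if (any(x < min) || any(x > max)) {
    stop(name, " out of range [", min, ", ", max, "]", call. = FALSE)
  }
  if (integer && any(x != floor(x))) {
    stop(name, " must be integer-valued", call. = FALSE)
  }
  invisible(x)
}

.check_flag <- function(x, name) {
  if (anyNA(x) || !(is.logical(x) || all(x %in% c(0, 1)))) {
    stop(name, " must be logical or 0/1", call. = FALSE)
  }
  invisible(x)
}
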