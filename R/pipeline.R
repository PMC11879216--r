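#' @title End-to-end validation pipeline
#' @description
#' Runs the full score-validation analysis on a schema-valid cohort:
#' scoring and stratification, week-8 escalation proportions, stratum-wise
#' and pooled Kaplan-Meier curves with escalation proportions at the
#' reporting horizons, the log-rank comparison of the two strata,
#' horizon diagnostic accuracy with Wilson intervals, the ROC over the
#' full 0-6 score, odds ratios per horizon, and the baseline comparison
#' table. The report is deterministic given the dataset.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param proportion_horizons Months at which stratum escalation
#'   proportions and odds ratios are reported (default 12, 24, 36).
#' @param diagnostic_horizons Months at which the 2x2 diagnostic accuracy
#'   is computed (default 36 and 48). The first is also the outcome
#'   horizon for the ROC.
#' @param conf_level Confidence level for all intervals.
#' @param event_cfg An [event_config()].
#' @return A list of class `premicc_validation_config`.
#' @export
validation_config <- function(proportion_horizons = c(12, 24, 36),
                              diagnostic_horizons = c(36, 48),
                              conf_level = 0.95,
                              event_cfg = event_config()) {
  stopifnot(all(proportion_horizons > 0), all(diagnostic_horizons > 0),
            conf_level > 0, conf_level < 1)
  structure(list(proportion_horizons = proportion_horizons,
                 diagnostic_horizons = diagnostic_horizons,
                 conf_level = conf_level, event_cfg = event_cfg),
            class = "premicc_validation_config")
}

#' Run the validation analysis on a cohort
#'
#' @param dataset A `premicc_cohort`.
#' @param cfg A [validation_config()].
#' @return An object of class `premicc_report`; see Details.
#' @details The report is a list with elements `n`, `stratum_sizes`,
#'   `week8` (overall and per-stratum escalation proportions), `km`
#'   (curves `overall`, `mild`, `severe`), `escalation_by_horizon`
#'   (1 - S(m) per stratum and horizon), `logrank`, `diagnostics` (per
#'   diagnostic horizon: cells, metrics, Wilson intervals), `roc`,
#'   `odds_ratios` (per horizon, as-observed counts, high-score group
#'   first) and `baseline_comparison`.
#' @export
run_validation <- function(dataset, cfg = validation_config()) {
  validate_cohort(dataset)
  if (nrow(dataset$baseline) == 0) {
    stop("empty dataset", call. = FALSE)
  }
  scores <- compute_score(dataset$baseline)
  tte <- build_tte_dataset(dataset, scores, cfg$event_cfg)
  mild <- tte$risk_class == "mild_predicted"

  tl <- cohort_timelines(dataset)
  w8 <- vapply(tl, assess_week8_escalation, logical(1), cfg = cfg$event_cfg)
  w8 <- w8[tte$patient_id]   # same order as tte

  km_overall <- km_fit(tte, cfg$conf_level)
  km_mild <- if (any(mild)) km_fit(tte[mild, ], cfg$conf_level) else NULL
  km_severe <- if (any(!mild)) km_fit(tte[!mild, ], cfg$conf_level) else NULL

  logrank <- if (!is.null(km_mild) && !is.null(km_severe)) {
    logrank_test(tte[!mild, ], tte[mild, ])   # high-score group first
  } else NULL

  esc <- lapply(cfg$proportion_horizons, function(m) {
    list(horizon_months = m,
         overall = 1 - survival_at(km_overall, m),
         mild = if (is.null(km_mild)) NA_real_ else
           1 - survival_at(km_mild, m),
         severe = if (is.null(km_severe)) NA_real_ else
           1 - survival_at(km_severe, m))
  })

  ors <- lapply(cfg$proportion_horizons, function(m) {
    if (!any(mild) || !any(!mild)) return(NULL)
    ea <- sum(!mild & tte$event & tte$time_months <= m)
    eb <- sum(mild & tte$event & tte$time_months <= m)
    c(list(horizon_months = m,
           escalated_high = ea, n_high = sum(!mild),
           escalated_low = eb, n_low = sum(mild)),
      odds_ratio(ea, sum(!mild), eb, sum(mild), cfg$conf_level))
  })

  diags <- lapply(cfg$diagnostic_horizons, function(m) {
    cm <- confusion_at_horizon(tte, m)
    met <- diagnostic_metrics(cm)
    wil <- list(
      sensitivity = wilson_ci(cm$tp, cm$tp + cm$fn, cfg$conf_level),
      specificity = wilson_ci(cm$tn, cm$tn + cm$fp, cfg$conf_level),
      ppv = wilson_ci(cm$tp, cm$tp + cm$fp, cfg$conf_level),
      npv = wilson_ci(cm$tn, cm$tn + cm$fn, cfg$conf_level))
    list(horizon_months = m, cells = unclass(cm), metrics = unclass(met),
         wilson = wil)
  })

  roc <- {
    m <- cfg$diagnostic_horizons[1]
    ev <- as.logical(tte$event)
    lbl_ok <- (ev & tte$time_months <= m) | tte$time_months >= m
    mild_course <- !(ev & tte$time_months <= m) & tte$time_months >= m
    tot <- scores$total[match(tte$patient_id, scores$patient_id)]
    df <- data.frame(total = tot[lbl_ok], mild = mild_course[lbl_ok])
    if (length(unique(df$mild)) == 2) {
      c(list(horizon_months = m), unclass(roc_auc(df)))
    } else NULL
  }

  comparison <- if (any(mild) && any(!mild)) {
    vars <- c("age_years", "crp_mg_dl", "endoscopic_gt1",
              "perianal_lesions", "stenosis", "fistula", "eim",
              "fever_gt38")
    b <- dataset$baseline
    hi <- b[b$patient_id %in% tte$patient_id[!mild], ]
    lo <- b[b$patient_id %in% tte$patient_id[mild], ]
    do.call(rbind, lapply(vars, function(v) {
      r <- compare_baseline(hi, lo, v)
      data.frame(variable = r$variable, test_name = r$test_name,
                 statistic = r$statistic, p_value = r$p_value,
                 significant = r$significant, stringsAsFactors = FALSE)
    }))
  } else NULL

  structure(list(
    n = nrow(dataset$baseline),
    stratum_sizes = list(mild = sum(mild), severe = sum(!mild)),
    week8 = list(overall = mean(w8),
                 mild = if (any(mild)) mean(w8[mild]) else NA_real_,
                 severe = if (any(!mild)) mean(w8[!mild]) else NA_real_),
    km = list(overall = km_overall, mild = km_mild, severe = km_severe),
    escalation_by_horizon = esc,
    logrank = if (is.null(logrank)) NULL else unclass(logrank),
    diagnostics = diags,
    roc = roc,
    odds_ratios = ors,
    baseline_comparison = comparison,
    scores = scores,
    tte = tte,
    config = list(proportion_horizons = cfg$proportion_horizons,
                  diagnostic_horizons = cfg$diagnostic_horizons,
                  conf_level = cfg$conf_level)
  ), class = "premicc_report")
}

#' Write a validation report to files
#'
#' Always writes `report.json` (full precision). The `csv` format adds the
#' per-stratum Kaplan-Meier tables (`km_overall.csv`, `km_mild.csv`,
#' `km_severe.csv`), `tte.csv`, `scores.csv`, `roc_points.csv` and
#' `baseline_comparison.csv`. The `plots` format adds PNG renderings of
#' the Kaplan-Meier curves and the ROC.
#'
#' @param report A `premicc_report`.
#' @param dir Output directory (created if absent).
#' @param formats Subset of `c("json", "csv", "plots")`.
#' @return `dir`, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "csv")) {
  if (!inherits(report, "premicc_report")) {
    stop("not a premicc_report", call. = FALSE)
  }
  unknown <- setdiff(formats, c("json", "csv", "plots"))
  if (length(unknown) > 0) {
    stop("unknown format(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_report <- report
  json_report$km <- lapply(report$km, function(k) {
    if (is.null(k)) NULL else as.data.frame(k)
  })
  jsonlite::write_json(unclass(json_report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  if ("csv" %in% formats) {
    for (nm in names(report$km)) {
      k <- report$km[[nm]]
      if (!is.null(k)) {
        utils::write.csv(as.data.frame(k),
                         file.path(dir, paste0("km_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
    tte_out <- report$tte
    tte_out$time_months <- round(tte_out$time_months, 6)
    tte_out$event <- as.integer(tte_out$event)
    utils::write.csv(tte_out, file.path(dir, "tte.csv"), row.names = FALSE)
    utils::write.csv(report$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE)
    if (!is.null(report$roc)) {
      utils::write.csv(report$roc$points, file.path(dir, "roc_points.csv"),
                       row.names = FALSE)
    }
    if (!is.null(report$baseline_comparison)) {
      utils::write.csv(report$baseline_comparison,
                       file.path(dir, "baseline_comparison.csv"),
                       row.names = FALSE)
    }
  }
  if ("plots" %in% formats) {
    .plot_km_png(report, file.path(dir, "km.png"))
    if (!is.null(report$roc)) .plot_roc_png(report, file.path(dir, "roc.png"))
  }
  invisible(dir)
}

.km_steps <- function(k, tmax) {
  if (is.null(k) || length(k$time) == 0) {
    return(list(x = c(0, tmax), y = c(1, 1)))
  }
  x <- c(0, rep(k$time, each = 2), tmax)
  y <- c(1, 1, rep(k$surv, each = 2))
  list(x = x, y = y[seq_along(x)])
}

.plot_km_png <- function(report, path) {
  tmax <- max(report$tte$time_months)
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  plot(NULL, xlim = c(0, tmax), ylim = c(0, 1),
       xlab = "Months since baseline", ylab = "Escalation-free proportion",
       main = "Time to therapy escalation by score class")
  cols <- c(overall = "grey40", mild = "forestgreen", severe = "firebrick")
  for (nm in names(report$km)) {
    s <- .km_steps(report$km[[nm]], tmax)
    graphics::lines(s$x, s$y, col = cols[[nm]], lwd = 2)
  }
  graphics::legend("bottomleft", legend = c("all", "score <= 2", "score > 2"),
                   col = cols, lwd = 2, bty = "n")
}

.plot_roc_png <- function(report, path) {
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  p <- report$roc$points
  plot(p$fpr, p$tpr, type = "b", pch = 19, xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC over the 0-6 score (AUC = %.3f)",
                      report$roc$auc))
  graphics::abline(0, 1, lty = 2, col = "grey")
}

#' @export
print.premicc_report <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", 100 * v))
  cat("PreMiCC validation report\n")
  cat("  patients: ", x$n, " (score <=2: ", x$stratum_sizes$mild,
      ", score >2: ", x$stratum_sizes$severe, ")\n", sep = "")
  cat("  week-8 escalation: ", pct(x$week8$overall), " overall (",
      pct(x$week8$mild), " / ", pct(x$week8$severe),
      " in score <=2 / >2)\n", sep = "")
  for (e in x$escalation_by_horizon) {
    cat("  escalation by month ", e$horizon_months, ": ",
        pct(e$mild), " (score <=2) vs ", pct(e$severe), " (score >2)\n",
        sep = "")
  }
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chi-square = %.2f, p = %.3g\n",
                x$logrank$chi_square, x$logrank$p_value))
  }
  for (d in x$diagnostics) {
    m <- d$metrics
    cat("  at ", d$horizon_months, " months: sensitivity ",
        pct(m$sensitivity), ", specificity ", pct(m$specificity),
        ", PPV ", pct(m$ppv), ", NPV ", pct(m$npv), "\n", sep = "")
  }
  if (!is.null(x$roc)) {
    cat(sprintf("  ROC AUC (horizon %g months): %.3f\n",
                x$roc$horizon_months, x$roc$auc))
  }
  invisible(x)
}
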