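#' @title Horizon diagnostic accuracy, ROC and group comparisons
#' @description
#' Evaluates the score as a classifier of the observed course at a fixed
#' time horizon. The positive prediction is the mild class (score <= 2) and
#' the condition positive is an actually mild course: no outcome failure by
#' the horizon with follow-up reaching it. Patients censored before the
#' horizon without an event carry no horizon label and are excluded
#' (complete-case horizon analysis); an event before the horizon makes the
#' course non-mild regardless of later follow-up.
#' @name diagnostics
NULL

#' Cross-classify score class against observed course at a horizon
#'
#' @param tte Time-to-event data frame from [build_tte_dataset()] (needs
#'   `time_months`, `event`, `risk_class`).
#' @param horizon_months Positive horizon (months).
#' @return A list of class `premicc_confusion` with integer cells `tp`
#'   (mild-predicted, mild course), `fp` (mild-predicted, escalated), `fn`
#'   (severe-predicted, mild course), `tn` (severe-predicted, escalated),
#'   plus `excluded` (censored before horizon) and `horizon_months`.
#' @export
confusion_at_horizon <- function(tte, horizon_months) {
  if (!is.numeric(horizon_months) || length(horizon_months) != 1 ||
      horizon_months <= 0) {
    stop("horizon_months must be a positive number", call. = FALSE)
  }
  ev <- as.logical(tte$event)
  event_by_h <- ev & tte$time_months <= horizon_months
  reached_h <- tte$time_months >= horizon_months
  excluded <- !ev & !reached_h
  cond_pos <- !event_by_h & reached_h        # mild course at horizon
  pred_pos <- tte$risk_class == "mild_predicted"
  keep <- !excluded
  structure(list(
    tp = sum(keep & pred_pos & cond_pos),
    fp = sum(keep & pred_pos & !cond_pos),
    fn = sum(keep & !pred_pos & cond_pos),
    tn = sum(keep & !pred_pos & !cond_pos),
    excluded = sum(excluded),
    horizon_months = horizon_months
  ), class = "premicc_confusion")
}

#' Diagnostic accuracy metrics from a 2x2 table
#'
#' Sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' npv = tn/(tn+fn). A metric whose denominator is zero is undefined and
#' returned as `NA` (never silently zero).
#'
#' @param cm A `premicc_confusion`, or a list with cells `tp`, `fp`, `fn`,
#'   `tn`.
#' @return A list of class `premicc_diagnostics` with `sensitivity`,
#'   `specificity`, `ppv`, `npv` (each `NA` when undefined) and
#'   `horizon_months` when the input carries one.
#' @export
diagnostic_metrics <- function(cm) {
  cells <- c("tp", "fp", "fn", "tn")
  vals <- unlist(cm[cells])
  if (anyNA(vals) || any(vals < 0)) {
    stop("confusion cells must be nonnegative counts", call. = FALSE)
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    horizon_months = cm$horizon_months %||% NA_real_
  ), class = "premicc_diagnostics")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilson score interval for a binomial proportion
#'
#' @param x Successes, `n` trials, `level` confidence level.
#' @param n,level See above.
#' @return Numeric vector `c(lower, upper)`; `NA`s when `n` is 0.
#' @export
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(lower = NA_real_, upper = NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' ROC curve and AUC over the integer score
#'
#' Sweeps the thresholds "predict mild when total <= k" for k = -1..6
#' (from predicting nobody mild to predicting everybody mild) against the
#' mild-course outcome, and integrates the resulting step curve by
#' trapezoids. Because lower scores indicate the positive (mild) class, the
#' trapezoidal AUC equals the concordance probability that a randomly
#' chosen mild patient has a lower score than a randomly chosen non-mild
#' patient, ties counted one half.
#'
#' @param scores Data frame with columns `total` (integer 0..6) and `mild`
#'   (logical outcome).
#' @return A list of class `premicc_roc`: `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores) {
  total <- scores$total
  mild <- as.logical(scores$mild)
  .check_numeric(total, "total", min = 0, max = 6, integer = TRUE)
  n_pos <- sum(mild)
  n_neg <- sum(!mild)
  if (n_pos == 0 || n_neg == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  ks <- -1:6
  tpr <- vapply(ks, function(k) sum(mild & total <= k) / n_pos, numeric(1))
  fpr <- vapply(ks, function(k) sum(!mild & total <= k) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = ks, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "premicc_roc")
}

#' Odds ratio for escalation between two groups
#'
#' Computes the cross-product odds ratio with a Woolf (log-scale normal)
#' confidence interval. When any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to every cell. By convention the first group is the
#' high-score (severe-predicted) group, so ratios above 1 mean more
#' escalation with scores above 2.
#'
#' @param escalated_a,total_a Escalations and group size in group A.
#' @param escalated_b,total_b Escalations and group size in group B.
#' @param level Confidence level.
#' @return A list with `or`, `ci_lower`, `ci_upper`, `level`.
#' @export
odds_ratio <- function(escalated_a, total_a, escalated_b, total_b,
                       level = 0.95) {
  .check_numeric(total_a, "total_a", min = 1, integer = TRUE)
  .check_numeric(total_b, "total_b", min = 1, integer = TRUE)
  .check_numeric(escalated_a, "escalated_a", min = 0, max = total_a,
                 integer = TRUE)
  .check_numeric(escalated_b, "escalated_b", min = 0, max = total_b,
                 integer = TRUE)
  cells <- c(escalated_a, total_a - escalated_a,
             escalated_b, total_b - escalated_b)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_lower = exp(log(or) - z * se),
       ci_upper = exp(log(or) + z * se), level = level)
}

#' Compare a baseline variable between the two score groups
#'
#' Categorical variables are compared with Pearson's chi-square test
#' (no continuity correction), switching to Fisher's exact test when any
#' expected cell count is 5 or below. Numeric variables are compared with the
#' two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction). Significance is flagged at p < .05, with no
#' multiple-testing adjustment across the baseline table.
#'
#' @param a,b Data frames of baseline records for the two groups.
#' @param variable Name of the column to compare. The derived variable
#'   `endoscopic_gt1` (endoscopic score above 1) is also accepted.
#' @param type `"auto"` (numeric columns -> rank-sum, 0/1 and derived
#'   columns -> categorical), `"numeric"` or `"categorical"`.
#' @return A list with `variable`, `test_name` (`chi-square`,
#'   `fisher-exact` or `wilcoxon-rank-sum`), `statistic`, `p_value`,
#'   `significant`.
#' @export
compare_baseline <- function(a, b, variable, type = c("auto", "numeric",
                                                      "categorical")) {
  type <- match.arg(type)
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  pull <- function(df) {
    if (variable == "endoscopic_gt1") {
      as.integer(df$endoscopic_score > 1)
    } else if (variable %in% names(df)) {
      df[[variable]]
    } else {
      stop("unknown baseline variable '", variable, "'", call. = FALSE)
    }
  }
  xa <- pull(a); xb <- pull(b)
  if (type == "auto") {
    flags <- c("perianal_lesions", "stenosis", "fistula", "eim",
               "fever_gt38", "endoscopic_gt1")
    type <- if (variable %in% flags) "categorical" else "numeric"
  }
  if (type == "categorical") {
    tab <- table(factor(c(xa, xb)),
                 rep(c("a", "b"), c(length(xa), length(xb))))
    if (nrow(tab) < 2) {
      # degenerate: variable constant in the pooled sample
      return(list(variable = variable, test_name = "chi-square",
                  statistic = 0, p_value = 1, significant = FALSE))
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 5)) {
      ft <- stats::fisher.test(tab)
      res <- list(test_name = "fisher-exact", statistic = NA_real_,
                  p_value = ft$p.value)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      res <- list(test_name = "chi-square",
                  statistic = unname(ct$statistic), p_value = ct$p.value)
    }
  } else {
    wt <- stats::wilcox.test(xa, xb, exact = FALSE, correct = FALSE)
    res <- list(test_name = "wilcoxon-rank-sum",
                statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  c(list(variable = variable), res,
    list(significant = res$p_value < 0.05))
}

#' @export
print.premicc_confusion <- function(x, ...) {
  cat(sprintf(
    "Horizon %.0f months: tp=%d fp=%d fn=%d tn=%d (excluded %d)\n",
    x$horizon_months, x$tp, x$fp, x$fn, x$tn, x$excluded))
  invisible(x)
}

#' @export
print.premicc_diagnostics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("sensitivity ", fmt(x$sensitivity), ", specificity ",
      fmt(x$specificity), ", PPV ", fmt(x$ppv), ", NPV ", fmt(x$npv), "\n",
      sep = "")
  invisible(x)
}
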