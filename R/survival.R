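#' @title Product-limit estimation and the two-sample log-rank test
#' @description
#' First-principles implementations of the nonparametric survival machinery
#' the score validation rests on: the Kaplan-Meier product-limit estimator
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), its Greenwood
#' variance S(t)^2 * sum d_i / (n_i (n_i - d_i)) with confidence bands on
#' the log(-log) scale, and the unweighted two-sample log-rank test with
#' hypergeometric variance at each distinct event time. Ties are handled
#' with the standard convention that events precede censorings at equal
#' times.
#' @name survival_stack
NULL

.tte_times <- function(records) {
  if (is.data.frame(records)) {
    list(time = records$time_months, event = as.logical(records$event))
  } else {
    stop("records must be a data frame with time_months and event",
         call. = FALSE)
  }
}

#' Fit a Kaplan-Meier curve
#'
#' @param records Data frame with columns `time_months` (positive) and
#'   `event` (logical or 0/1); typically the output of
#'   [build_tte_dataset()].
#' @param conf_level Confidence level for the Greenwood log(-log) bands.
#' @return An object of class `premicc_km`: a list with vectors `time`
#'   (distinct event times, ascending), `n_risk`, `n_event`, `surv`, `se`
#'   (Greenwood standard error), `lower`, `upper`, and scalars `n`,
#'   `conf_level`. With no events all vectors are empty and the curve is
#'   identically 1.
#' @export
km_fit <- function(records, conf_level = 0.95) {
  d <- .tte_times(records)
  if (length(d$time) == 0) stop("no observations", call. = FALSE)
  if (anyNA(d$time) || any(d$time <= 0)) {
    stop("all times must be positive and non-missing", call. = FALSE)
  }
  ev_times <- sort(unique(d$time[d$event]))
  n_risk <- vapply(ev_times, function(t) sum(d$time >= t), numeric(1))
  n_event <- vapply(ev_times, function(t) sum(d$time == t & d$event),
                    numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw_terms <- n_event / (n_risk * (n_risk - n_event))
  gw_terms[n_risk == n_event] <- Inf
  cumvar <- cumsum(gw_terms)
  se <- surv * sqrt(cumvar)
  se[surv == 0] <- 0
  curve <- structure(list(time = ev_times, n_risk = as.integer(n_risk),
                          n_event = as.integer(n_event), surv = surv,
                          se = se, lower = NULL, upper = NULL,
                          n = length(d$time), conf_level = conf_level,
                          cumvar = cumvar),
                     class = "premicc_km")
  greenwood_ci(curve, conf_level)
}

#' Add Greenwood confidence bands to a fitted curve
#'
#' Bands are computed on the complementary log-log scale,
#' `S^exp(-+ z * se(log(-log S)))`, which keeps them inside \[0, 1\]; at
#' S = 1 the band is degenerate at 1 and at S = 0 at 0.
#'
#' @param curve A `premicc_km` object.
#' @param level Confidence level in (0, 1).
#' @return The curve with `lower`, `upper` and `conf_level` replaced.
#' @export
greenwood_ci <- function(curve, level = 0.95) {
  if (!inherits(curve, "premicc_km")) stop("not a premicc_km", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("conf level must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- curve$surv
  lower <- upper <- s
  mid <- s > 0 & s < 1
  if (any(mid)) {
    se_cll <- sqrt(curve$cumvar[mid]) / abs(log(s[mid]))
    lower[mid] <- s[mid]^exp(z * se_cll)
    upper[mid] <- s[mid]^exp(-z * se_cll)
  }
  curve$lower <- pmin(pmax(lower, 0), 1)
  curve$upper <- pmin(pmax(upper, 0), 1)
  curve$conf_level <- level
  curve
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation: the value at the latest event
#' time at or before `t`, and 1 before the first event.
#'
#' @param curve A `premicc_km` object.
#' @param t Nonnegative time (months); vectorised.
#' @return Survival probabilities in \[0, 1\].
#' @export
survival_at <- function(curve, t) {
  if (!inherits(curve, "premicc_km")) stop("not a premicc_km", call. = FALSE)
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (length(curve$time) == 0) return(rep(1, length(t)))
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0, 1, curve$surv[pmax(idx, 1)])
}

#' Two-sample log-rank test
#'
#' Unweighted log-rank test comparing the event-time distributions of two
#' groups. At each distinct event time the observed events in group A are
#' compared with the expectation under the null (proportional to the group's
#' share of the risk set), with the hypergeometric variance
#' `d (n_A/n) (1 - n_A/n) (n - d)/(n - 1)`. The statistic
#' `(O_A - E_A)^2 / V` is referred to the chi-square distribution with one
#' degree of freedom (upper tail, no continuity correction).
#'
#' @param a,b Data frames with `time_months` and `event` for the two groups.
#' @return A list of class `premicc_logrank`: `chi_square`, `p_value`,
#'   `observed` and `expected` (length-2 vectors, groups in argument
#'   order), `df`.
#' @export
logrank_test <- function(a, b) {
  da <- .tte_times(a); db <- .tte_times(b)
  if (length(da$time) == 0 || length(db$time) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  time <- c(da$time, db$time)
  event <- c(da$event, db$event)
  grp_a <- c(rep(TRUE, length(da$time)), rep(FALSE, length(db$time)))
  ev_times <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  o_b <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp_a)
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & grp_a)
    o_a <- o_a + d_a
    o_b <- o_b + (d - d_a)
    e_a <- e_a + d * n_a / n
    if (n > 1) {
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
    }
  }
  chi <- if (v > 0) (o_a - e_a)^2 / v else 0
  total_events <- o_a + o_b
  structure(list(chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 observed = c(o_a, o_b),
                 expected = c(e_a, total_events - e_a),
                 df = 1L),
            class = "premicc_logrank")
}

#' @export
print.premicc_km <- function(x, ...) {
  cat("Kaplan-Meier curve: n = ", x$n, ", ", length(x$time),
      " distinct event times\n", sep = "")
  if (length(x$time) > 0) {
    print(as.data.frame(x)[seq_len(min(10, length(x$time))), ],
          row.names = FALSE)
    if (length(x$time) > 10) cat("...\n")
  }
  invisible(x)
}

#' @export
as.data.frame.premicc_km <- function(x, ...) {
  data.frame(time_months = x$time, at_risk = x$n_risk, events = x$n_event,
             survival = x$surv, se = x$se, ci_lower = x$lower,
             ci_upper = x$upper)
}

#' @export
print.premicc_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("  observed: %.0f / %.0f   expected: %.2f / %.2f\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2]))
  invisible(x)
}
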