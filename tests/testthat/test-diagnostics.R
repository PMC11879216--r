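test_that("horizon cross-classification follows the complete-case rule", {
  tte <- tte_df(c(10, 10, 20, 40, 36),
                c(TRUE, TRUE, FALSE, FALSE, FALSE),
                c("mild_predicted", "severe_predicted", "mild_predicted",
                  "severe_predicted", "mild_predicted"))
  cm <- confusion_at_horizon(tte, 36)
  # mild-predicted with an event at month 10 -> fp
  # severe-predicted with an event at month 10 -> tn
  # mild-predicted censored at 20 -> excluded
  # severe-predicted censored at 40 -> fn; mild censored exactly at 36 -> tp
  expect_equal(cm$tp, 1); expect_equal(cm$fp, 1)
  expect_equal(cm$fn, 1); expect_equal(cm$tn, 1)
  expect_equal(cm$excluded, 1)
  expect_error(confusion_at_horizon(tte, -1), "positive")
})

test_that("an event before the horizon dominates later follow-up", {
  tte <- tte_df(c(10), TRUE, "severe_predicted")
  tte$time_months <- 10
  cm <- confusion_at_horizon(tte, 36)
  expect_equal(cm$tn, 1)
  # same patient, horizon before the event: censored-like but event known
  cm2 <- confusion_at_horizon(tte_df(30, TRUE, "severe_predicted"), 20)
  expect_equal(cm2$fn, 1)  # event after horizon, follow-up reaches it
})

test_that("diagnostic metrics reproduce the validation triple exactly", {
  m <- diagnostic_metrics(list(tp = 20, fn = 2, fp = 5, tn = 18))
  expect_equal(m$sensitivity, 20 / 22)
  expect_equal(m$specificity, 18 / 23)
  expect_equal(m$ppv, 20 / 25)
  expect_equal(round(100 * m$sensitivity, 1), 90.9)
  expect_equal(round(100 * m$specificity, 1), 78.3)
  expect_equal(round(100 * m$ppv, 1), 80.0)

  u <- diagnostic_metrics(list(tp = 0, fn = 0, fp = 3, tn = 7))
  expect_true(is.na(u$sensitivity))
  expect_equal(u$specificity, 0.7)

  p <- diagnostic_metrics(list(tp = 9, fn = 0, fp = 0, tn = 4))
  expect_equal(unlist(p[c("sensitivity", "specificity", "ppv", "npv")],
                      use.names = FALSE), rep(1, 4))
})

test_that("ppv is consistent with sensitivity, specificity and prevalence", {
  set.seed(13)
  for (i in 1:30) {
    cm <- list(tp = sample(1:30, 1), fp = sample(1:30, 1),
               fn = sample(1:30, 1), tn = sample(1:30, 1))
    m <- diagnostic_metrics(cm)
    n <- cm$tp + cm$fp + cm$fn + cm$tn
    prev <- (cm$tp + cm$fn) / n
    expect_equal(m$ppv,
                 m$sensitivity * prev /
                   (m$sensitivity * prev + (1 - m$specificity) * (1 - prev)))
  }
})

test_that("threshold-sweep AUC equals pairwise concordance", {
  conc_auc <- function(total, mild) {
    pos <- total[mild]; neg <- total[!mild]
    s <- 0
    for (p in pos) for (q in neg) {
      s <- s + (p < q) + 0.5 * (p == q)   # low score predicts mild
    }
    s / (length(pos) * length(neg))
  }
  toy <- data.frame(total = c(1, 1, 4, 0),
                    mild = c(TRUE, FALSE, FALSE, TRUE))
  r <- roc_auc(toy)
  expect_equal(r$auc, conc_auc(toy$total, toy$mild))
  expect_equal(r$auc, 0.875)
  expect_equal(r$points$fpr[1], 0); expect_equal(r$points$tpr[1], 0)
  expect_equal(r$points$fpr[8], 1); expect_equal(r$points$tpr[8], 1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))

  sep <- data.frame(total = c(0, 1, 5, 6), mild = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(roc_auc(sep)$auc, 1)
  ties <- data.frame(total = rep(3, 6), mild = rep(c(TRUE, FALSE), 3))
  expect_equal(roc_auc(ties)$auc, 0.5)
  expect_error(roc_auc(data.frame(total = 1:3, mild = TRUE)), "both")

  set.seed(17)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    df <- data.frame(total = sample(0:6, n, replace = TRUE),
                     mild = stats::runif(n) < 0.5)
    if (length(unique(df$mild)) < 2) next
    expect_equal(roc_auc(df)$auc, conc_auc(df$total, df$mild))
  }
})

test_that("odds ratios follow the cross-product with Woolf intervals", {
  expect_equal(odds_ratio(10, 20, 10, 20)$or, 1)

  r <- odds_ratio(79, 113, 21, 88)
  expect_equal(r$or, (79 / 34) / (21 / 67))
  expect_equal(round(r$or, 2), 7.41)
  se <- sqrt(1 / 79 + 1 / 34 + 1 / 21 + 1 / 67)
  expect_equal(r$ci_lower, exp(log(r$or) - stats::qnorm(0.975) * se))

  # zero cell: Haldane-Anscombe correction keeps the estimate finite
  r0 <- odds_ratio(5, 5, 0, 10)
  expect_true(is.finite(r0$or) && r0$or > 1)

  a <- odds_ratio(15, 40, 5, 35)
  b <- odds_ratio(5, 35, 15, 40)
  expect_equal(a$or, 1 / b$or)
  expect_error(odds_ratio(1, 0, 1, 5), "total_a")
})

test_that("baseline comparisons pick the documented test and match oracles", {
  g <- baseline_rec(c(30, 40, 50, 60), c(1, 2, 3, 4), c(0, 1, 2, 3),
                    c(0, 0, 1, 0))
  same <- compare_baseline(g, g, "age_years")
  expect_equal(same$test_name, "wilcoxon-rank-sum")
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  # rank-sum statistic for fully separated tiny samples (Mann-Whitney U = 0)
  a <- baseline_rec(age_years = c(1, 2, 3))
  b <- baseline_rec(age_years = c(4, 5, 6))
  r <- compare_baseline(a, b, "age_years")
  expect_equal(unname(r$statistic), 0)

  # Fisher exact p against exhaustive hypergeometric tail enumeration
  a <- baseline_rec(perianal_lesions = c(1, rep(0, 9)))
  b <- baseline_rec(perianal_lesions = c(rep(1, 9), 0))
  r <- compare_baseline(a, b, "perianal_lesions")
  expect_equal(r$test_name, "fisher-exact")
  x_obs <- 1  # group-a positives; margins: 10 positives, 10 per group
  probs <- stats::dhyper(0:10, 10, 10, 10)
  oracle_p <- sum(probs[probs <= stats::dhyper(x_obs, 10, 10, 10) + 1e-12])
  expect_equal(r$p_value, oracle_p, tolerance = 1e-10)

  # large balanced table: Pearson chi-square against direct CDF evaluation
  a <- baseline_rec(perianal_lesions = rep(c(1, 0), c(30, 70)))
  b <- baseline_rec(perianal_lesions = rep(c(1, 0), c(50, 50)))
  r <- compare_baseline(a, b, "perianal_lesions")
  expect_equal(r$test_name, "chi-square")
  tab <- rbind(c(70, 50), c(30, 50))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(unname(r$statistic), stat)
  expect_equal(r$p_value, stats::pchisq(stat, 1, lower.tail = FALSE))
  expect_true(r$significant)

  expect_error(compare_baseline(a[0, ], b, "perianal_lesions"), "nonempty")
  expect_error(compare_baseline(a, b, "nope"), "unknown baseline variable")
})
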