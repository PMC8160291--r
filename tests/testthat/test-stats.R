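# ROC/cutoff, survival, group-comparison and agreement statistics.

test_that("AUC toys: perfect separation, complete ties, pairwise enumeration", {
  r <- roc_auc_and_cutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(roc_auc_and_cutoff(rep(0.5, 8), rep(c(1, 0), 4))$auc, 0.5)
  # positives {2, 0}, negatives {3, 1}: one win of four pairs
  expect_equal(roc_auc_and_cutoff(c(2, 0, 3, 1), c(1, 1, 0, 0))$auc, 0.25)
  expect_error(roc_auc_and_cutoff(1:4, rep(1, 4)),
               class = "radscore_spec_error")
})

test_that("Youden cutoff uses the > calling convention with spec tie-break", {
  scores <- c(0.1, 0.2, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  r <- roc_auc_and_cutoff(scores, labels)
  expect_equal(r$cutoff, 0.2)   # calls both positives, no negatives
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
})

test_that("AUC invariants: complement symmetry and trapezoid agreement", {
  set.seed(5)
  for (i in 1:5) {
    scores <- rnorm(40)  # tie-free
    labels <- rbinom(40, 1, 0.4)
    if (length(unique(labels)) < 2) next
    a1 <- roc_auc_and_cutoff(scores, labels)$auc
    a2 <- roc_auc_and_cutoff(-scores, labels)$auc
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
    cv <- roc_auc_and_cutoff(scores, labels)$curve
    trap <- sum(diff(cv$fpr) * (head(cv$tpr, -1) + tail(cv$tpr, -1)) / 2)
    expect_equal(a1, trap, tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier product-limit hand examples", {
  fit <- km_logrank(c(5, 10), c(1, 1))
  expect_equal(fit$km_curves$survival, c(0.5, 0))
  # all censored: survival stays at 1
  fit2 <- km_logrank(c(3, 8, 11), c(0, 0, 0))
  expect_true(all(fit2$km_curves$survival == 1))
  # no censoring: KM equals 1 - empirical CDF at event times
  set.seed(9)
  tt <- sort(rexp(30, 0.1))
  fit3 <- km_logrank(tt, rep(1, 30))
  expect_equal(fit3$km_curves$survival,
               1 - seq_along(tt) / 30, tolerance = 1e-12)
})

test_that("log-rank: identical groups give statistic 0, relabel invariance", {
  tt <- c(5, 8, 12, 20, 30, 31); ev <- c(1, 0, 1, 1, 0, 1)
  fit <- km_logrank(rep(tt, 2), rep(ev, 2), rep(c("a", "b"), each = 6))
  expect_equal(fit$logrank_stat, 0, tolerance = 1e-12)
  set.seed(4)
  t2 <- rexp(40, 0.05); e2 <- rbinom(40, 1, 0.7)
  g2 <- rep(c("x", "y"), 20)
  f1 <- km_logrank(t2, e2, g2)
  f2 <- km_logrank(t2, e2, ifelse(g2 == "x", "y", "x"))
  expect_equal(f1$logrank_stat, f2$logrank_stat, tolerance = 1e-12)
})

test_that("Cox univariate gate: only passing covariates enter multivariate", {
  set.seed(12)
  n <- 300
  strong <- rbinom(n, 1, 0.5)
  noise <- rnorm(n)
  rate <- 0.02 * exp(1.5 * strong)
  tt <- rexp(n, rate); cens <- runif(n, 10, 80)
  ev <- as.integer(tt <= cens); tt <- pmin(tt, cens)
  fit <- cox_ph(data.frame(strong = strong, noise = noise), tt, ev)
  expect_identical(fit$multivariate_vars, "strong")
  expect_error(cox_ph(data.frame(x = rnorm(5)), 1:5, rep(0, 5)),
               class = "radscore_spec_error")
})

test_that("group table: chi-square rows reproduce the resection-extent p-value", {
  # 2x2 counts GTR/STR x event from a 128-patient series: p ~ 0.007
  cohort <- data.frame(
    resection = rep(c("GTR", "GTR", "STR", "STR"), c(9, 84, 10, 25)),
    event = rep(c(1, 0, 1, 0), c(9, 84, 10, 25)))
  tab <- cohort_table_stats(cohort, group = "event")
  expect_equal(tab$test, "chisq")
  expect_equal(tab$p, 0.007364963, tolerance = 1e-6)
  # small expected cell -> Fisher routing
  cohort2 <- data.frame(x = rep(c("a", "b"), c(4, 40)),
                        event = c(rep(1, 3), rep(0, 1), rep(1, 5),
                                  rep(0, 35)))
  expect_equal(cohort_table_stats(cohort2, group = "event")$test, "fisher")
  # identical continuous distributions: Mann-Whitney p near 1
  cohort3 <- data.frame(x = rep(seq(0, 1, length.out = 50), 2),
                        event = rep(c(0, 1), each = 50))
  expect_gt(cohort_table_stats(cohort3, group = "event")$p, 0.9)
  expect_warning(
    cohort_table_stats(data.frame(x = rep("a", 20),
                                  event = rep(c(0, 1), 10)),
                       group = "event"), "single level")
})

test_that("group_rates reproduces per-group percentages", {
  counts <- matrix(c(9, 10, 84, 25), 2,
                   dimnames = list(c("GTR", "STR"), c("event", "none")))
  gr <- group_rates(counts)
  expect_equal(gr$rate_percent, c(9.7, 28.6))
  expect_equal(group_rates(matrix(c(0, 2, 10, 8), 2))$rate_percent[1], 0)
  expect_error(group_rates(matrix(c(0, 1, 0, 1), 2)),
               class = "radscore_spec_error")
})

test_that("ICC(2,1): perfect agreement, planted variance ratio, and null", {
  set.seed(21)
  x <- rnorm(30)
  expect_equal(icc_agreement(cbind(x, x)), 1)
  # subject variance 4, error variance 1 -> ICC = 0.8
  iccs <- vapply(1:200, function(i) {
    subj <- rnorm(50, sd = 2)
    icc_agreement(cbind(subj + rnorm(50), subj + rnorm(50)))
  }, 0)
  expect_lt(abs(mean(iccs) - 0.8), 0.05)
  # independent noise: ICC near 0
  iccs0 <- vapply(1:200, function(i)
    icc_agreement(cbind(rnorm(50), rnorm(50))), 0)
  expect_lt(abs(mean(iccs0)), 0.1)
  expect_warning(v <- icc_agreement(matrix(1, 5, 2)), "between-subject")
  expect_equal(v, 0)
})

test_that("logistic combination of SVM score and ADC yields a valid ROC", {
  set.seed(31)
  n <- 120
  ev <- rbinom(n, 1, 0.3)
  svm <- 0.3 + 0.5 * ev + rnorm(n, sd = 0.3)
  adc <- 0.87 - 0.08 * ev + rnorm(n, sd = 0.06)
  comb <- combined_roc(svm, adc, ev)
  expect_gte(comb$auc, roc_auc_and_cutoff(svm, ev)$auc - 0.05)
  expect_true(comb$auc >= 0 && comb$auc <= 1)
})
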