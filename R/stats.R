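# Evaluation statistics: ROC with Youden cutoff, Kaplan-Meier / log-rank,
# univariate-gated multivariate Cox (Efron ties), group-comparison tables
# (chi-square without continuity correction, Fisher routing on small
# expected counts, Mann-Whitney U), per-group event rates, and ICC(2,1).
# Survival machinery is delegated to the survival package; the ROC, rate
# and ICC computations are self-contained.

#' ROC curve, AUC and Youden-optimal cutoff
#'
#' AUC is the normalized Mann-Whitney U statistic (ties counted 1/2).  The
#' cutoff is the observed score maximizing Youden's J = sensitivity +
#' specificity - 1 with the calling convention "positive when score >
#' cutoff"; J ties break toward higher specificity.
#'
#' @param scores numeric risk scores.
#' @param labels binary outcome (0/1, logical, or -1/+1).
#' @return list of class `roc_result`: `auc`, `cutoff`, `sensitivity`,
#'   `specificity`, and `curve` (data frame of threshold / tpr / fpr).
#' @export
roc_auc_and_cutoff <- function(scores, labels) {
  labels <- as.integer(as.numeric(labels) > 0)
  if (length(unique(labels)) < 2)
    stop_radscore("both classes must be present", "radscore_spec_error")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- sort(unique(scores))
  stats <- vapply(thr, function(ct) {
    called <- scores > ct
    c(sens = sum(called & labels == 1) / npos,
      spec = sum(!called & labels == 0) / nneg)
  }, c(sens = 0, spec = 0))
  j <- stats["sens", ] + stats["spec", ] - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(stats["spec", best])]
  curve <- data.frame(threshold = c(-Inf, thr),
                      tpr = c(1, stats["sens", ]),
                      fpr = c(1, 1 - stats["spec", ]))
  structure(list(auc = auc, cutoff = thr[best],
                 sensitivity = unname(stats["sens", best]),
                 specificity = unname(stats["spec", best]),
                 curve = curve[order(curve$fpr, curve$tpr), ]),
            class = "roc_result")
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit estimator per group plus the (k-1)-df log-rank chi-square
#' (NA when a single group is supplied).
#'
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param groups group labels (any atomic type).
#' @return list of class `survival_fit`: `km_curves` (per-group data frame
#'   of time / survival / at-risk), `logrank_stat`, `logrank_p`.
#' @export
km_logrank <- function(times, events, groups = rep(1, length(times))) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0) || nlevels(groups) == 0)
    stop_radscore("every group needs at least one subject",
                  "radscore_spec_error")
  sf <- survival::survfit(survival::Surv(times, events) ~ groups)
  smry <- summary(sf, censored = TRUE)
  grp <- if (is.null(smry$strata)) rep(levels(groups)[1], length(smry$time))
         else sub("^groups=", "", as.character(smry$strata))
  km <- data.frame(group = grp, time = smry$time, survival = smry$surv,
                   n_risk = smry$n.risk, n_event = smry$n.event)
  if (nlevels(groups) > 1) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    stat <- sd$chisq
    p <- pchisq(stat, df = nlevels(groups) - 1, lower.tail = FALSE)
  } else {
    stat <- NA_real_; p <- NA_real_
  }
  structure(list(km_curves = km, logrank_stat = stat, logrank_p = p),
            class = "survival_fit")
}

#' Univariate-gated multivariate Cox proportional hazards
#'
#' Fits a univariate Cox model per covariate (Efron tie handling);
#' covariates with univariate Wald p below `gate_p` are refit jointly.
#'
#' @param covariate_table data frame of numeric covariates (binary ones
#'   coded 0/1).
#' @param times follow-up times.
#' @param events event indicators (0/1).
#' @param gate_p univariate inclusion threshold for the multivariate model.
#' @return list of class `cox_fit`: `table` (variable, hr, ci_low, ci_high,
#'   p, analysis in {"univariate","multivariate"}) and `multivariate_vars`.
#' @export
cox_ph <- function(covariate_table, times, events, gate_p = 0.05) {
  covariate_table <- as.data.frame(covariate_table)
  if (sum(events) < 1)
    stop_radscore("no events: Cox model undefined", "radscore_spec_error")
  srv <- survival::Surv(times, events)
  one <- function(df, vars, analysis) {
    fit <- survival::coxph(srv ~ ., data = df[, vars, drop = FALSE],
                           ties = "efron")
    if (!is.null(fit$info) || any(is.na(coef(fit))))
      stop_radscore("Cox model did not converge (perfect separation?)",
                    "radscore_convergence_error")
    s <- summary(fit)
    data.frame(variable = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               ci_low = s$conf.int[, "lower .95"],
               ci_high = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               analysis = analysis, row.names = NULL)
  }
  uni <- do.call(rbind, lapply(names(covariate_table), function(v)
    one(covariate_table, v, "univariate")))
  keep <- uni$variable[uni$p < gate_p]
  multi <- if (length(keep) >= 1)
    one(covariate_table, keep, "multivariate") else NULL
  structure(list(table = rbind(uni, multi), multivariate_vars = keep),
            class = "cox_fit")
}

#' Group-comparison table for a cohort
#'
#' Categorical variables: chi-square without continuity correction, routed
#' to Fisher's exact test when any expected cell count is below 5.
#' Continuous variables: two-sided Mann-Whitney U.  Variables with a single
#' observed level are skipped with a warning.
#'
#' @param cohort data frame.
#' @param group name of the binary grouping column (e.g. `"event"`).
#' @param variables columns to compare; default all others.
#' @return data frame: variable, test used, statistic, p value.
#' @export
cohort_table_stats <- function(cohort, group = "event", variables = NULL) {
  g <- as.factor(cohort[[group]])
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop_radscore("both outcome groups must be nonempty",
                  "radscore_spec_error")
  if (is.null(variables))
    variables <- setdiff(names(cohort), group)
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    categorical <- is.character(x) || is.factor(x) || is.logical(x) ||
      length(unique(x[!is.na(x)])) <= 2
    if (length(unique(x[!is.na(x)])) < 2) {
      warning(sprintf("variable '%s' has a single level: skipped", v))
      return(NULL)
    }
    if (categorical) {
      tab <- table(factor(x), g)
      expected <- suppressWarnings(chisq.test(tab, correct = FALSE)$expected)
      if (any(expected < 5)) {
        ft <- fisher.test(tab)
        data.frame(variable = v, test = "fisher", statistic = NA_real_,
                   p = ft$p.value)
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        data.frame(variable = v, test = "chisq",
                   statistic = unname(ct$statistic), p = ct$p.value)
      }
    } else {
      wt <- suppressWarnings(wilcox.test(as.numeric(x) ~ g))
      data.frame(variable = v, test = "mann-whitney",
                 statistic = unname(wt$statistic), p = wt$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Per-group event proportions
#'
#' @param counts 2x2 integer matrix: rows = groups, columns = (events,
#'   non-events).  Row names label the groups.
#' @return data frame: group, events, total, and the event rate in percent
#'   rounded to one decimal.
#' @export
group_rates <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), ncol(counts) == 2)
  totals <- rowSums(counts)
  if (any(totals == 0))
    stop_radscore("zero group total", "radscore_spec_error")
  data.frame(group = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             events = counts[, 1], total = totals,
             rate_percent = round(100 * counts[, 1] / totals, 1),
             row.names = NULL)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single rater, from the
#' standard mean squares: `(MSR - MSE) / (MSR + (k-1) MSE +
#' k (MSC - MSE) / n)`.
#'
#' @param ratings numeric matrix, subjects x raters (>= 3 subjects, >= 2
#'   raters).
#' @return ICC value; 0 with a warning when there is no between-subject
#'   variance.
#' @export
icc_agreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2)
    stop_radscore("need >= 3 subjects and >= 2 raters",
                  "radscore_spec_error")
  if (var(rowMeans(ratings)) == 0) {
    warning("zero between-subject variance: ICC reported as 0")
    return(0)
  }
  grand <- mean(ratings)
  msr <- k * sum((rowMeans(ratings) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(ratings) - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowMeans(ratings), rep(1, k)) -
                outer(rep(1, n), colMeans(ratings)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

#' ROC of a logistic combination of SVM score and ADC
#'
#' The combination rule behind a joint imaging model is not canonical; this
#' package combines the two predictors by logistic regression and reports
#' the ROC of the fitted linear predictor.
#'
#' @param svm_scores,adc_values numeric predictors.
#' @param labels binary outcome.
#' @return a `roc_result` (see [roc_auc_and_cutoff()]) with the fitted
#'   `glm` attached as attribute `"model"`.
#' @export
combined_roc <- function(svm_scores, adc_values, labels) {
  labels <- as.integer(as.numeric(labels) > 0)
  fit <- glm(labels ~ svm_scores + adc_values, family = binomial())
  res <- roc_auc_and_cutoff(predict(fit, type = "link"), labels)
  attr(res, "model") <- fit
  res
}
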