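#' Empirical ROC curve and AUC
#'
#' Builds the empirical ROC step curve of a continuous score against 0/1
#' labels (higher score = more likely positive). Candidate cutoffs are the
#' midpoints between adjacent distinct score values plus the two infinite
#' endpoints; a sample is called positive when its score is at least the
#' cutoff. The trapezoidal AUC equals the tie-corrected Mann-Whitney
#' statistic.
#'
#' @param scores Numeric vector.
#' @param labels 0/1 vector aligned with scores; both classes required.
#' @return An object of class `roc_result` with `points` (data frame of
#'   cutoff, sensitivity, specificity, tp/fp/tn/fn), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  cuts <- roc_cutoffs(scores)
  tp <- vapply(cuts, function(c) sum(scores >= c & labels == 1), 0)
  fp <- vapply(cuts, function(c) sum(scores >= c & labels == 0), 0)
  sens <- tp / n_pos
  spec <- 1 - fp / n_neg
  ord <- order(1 - spec, sens)
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(cutoff = cuts, sensitivity = sens,
                             specificity = spec, tp = tp, fp = fp,
                             tn = n_neg - fp, fn = n_pos - tp),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

# Midpoints between adjacent distinct score values, plus -Inf / +Inf.
roc_cutoffs <- function(scores) {
  s <- sort(unique(scores))
  if (length(s) == 1) return(c(-Inf, Inf))
  c(-Inf, (utils::head(s, -1) + utils::tail(s, -1)) / 2, Inf)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.4f (%d positives, %d negatives, %d cutoffs)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  invisible(x)
}

#' Youden best point of a ROC curve
#'
#' The cutoff maximizing Youden's J = sensitivity + specificity - 1. Ties
#' are broken in favor of higher specificity, then the larger cutoff.
#' Predictive values are computed at the evaluation set's prevalence.
#'
#' @param roc A `roc_result`.
#' @return List with `cutoff`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `youden_j`.
#' @export
youden_best_point <- function(roc) {
  pts <- roc$points
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j > max(j) - 1e-12)
  if (length(best) > 1) {
    best <- best[order(-pts$specificity[best], -pts$cutoff[best])][1]
  }
  tp <- pts$tp[best]; fp <- pts$fp[best]
  tn <- pts$tn[best]; fn <- pts$fn[best]
  list(cutoff = pts$cutoff[best],
       sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best],
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       youden_j = j[best])
}

#' Stratified percentile bootstrap confidence intervals
#'
#' Resamples the evaluation set within each class (so every replicate
#' keeps both classes at their observed sizes), applies the metric
#' function, and returns percentile 95% intervals. The metric may return a
#' named vector, giving one interval per metric.
#'
#' @param metric_fn Function of (scores, labels) returning a numeric
#'   scalar or named vector.
#' @param scores,labels The evaluation set.
#' @param n Number of replicates (default 2000, minimum 100).
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @param conf Confidence level (default 0.95).
#' @return Matrix with one row per metric and columns `lower`, `upper`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n = 2000, seed = NULL,
                         conf = 0.95) {
  if (n < 100) stop("at least 100 bootstrap replicates required")
  if (!is.null(seed)) set.seed(seed)
  i0 <- which(labels == 0); i1 <- which(labels == 1)
  reps <- vapply(seq_len(n), function(b) {
    idx <- c(sample(i0, length(i0), replace = TRUE),
             sample(i1, length(i1), replace = TRUE))
    as.numeric(metric_fn(scores[idx], labels[idx]))
  }, FUN.VALUE = as.numeric(metric_fn(scores, labels)))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  alpha <- (1 - conf) / 2
  ci <- t(apply(reps, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  rownames(ci) <- names(metric_fn(scores, labels))
  colnames(ci) <- c("lower", "upper")
  ci
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function under right-censoring.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return An object of class `km_curve`: data frame with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty input")
  if (any(times <= 0)) stop("times must be positive")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability from a Kaplan-Meier curve
#'
#' Step-function lookup: S(t) with S(0) = 1.
#' @param km A `km_curve`.
#' @param t Time at which to evaluate.
#' @export
km_survival_at <- function(km, t) {
  s <- c(1, km$survival)
  idx <- findInterval(t, km$time) + 1
  s[idx]
}

#' Two-group logrank test
#'
#' Standard logrank chi-square test (1 df) with hypergeometric variance.
#'
#' @param times,events Survival outcome.
#' @param group Two-level grouping vector.
#' @return List with `statistic` (chi-square), `p`, `observed`,
#'   `expected`, and the signed standardized statistic `z` for the first
#'   group level.
#' @export
logrank_test <- function(times, events, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two non-empty groups required")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  z <- (sd_$obs[1] - sd_$exp[1]) / sqrt(sd_$var[1, 1])
  list(statistic = sd_$chisq,
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp, z = z)
}

#' Cox proportional-hazards summaries
#'
#' Fits Cox models (Breslow ties) and reports hazard ratios with Wald 95%
#' confidence intervals and p-values. In univariate mode each covariate is
#' fitted alone; in multivariate mode all covariates enter one model.
#' Ordinal covariates (stage, ASA) should be passed as integers; factors
#' are dummy-coded against their first level. Rows with missing covariate
#' values are dropped and counted.
#'
#' @param times,events Survival outcome.
#' @param covariates Data frame of covariates.
#' @param multivariate Fit one joint model (default FALSE = univariate
#'   loop).
#' @return Data frame with `term`, `hr`, `lower`, `upper`, `p`, `n`,
#'   `n_event`, `n_dropped`.
#' @export
cox_ph <- function(times, events, covariates, multivariate = FALSE) {
  covariates <- as.data.frame(covariates)
  if (sum(events) < 10) stop("at least 10 events required")
  fit_one <- function(df) {
    keep <- stats::complete.cases(df)
    n_dropped <- sum(!keep)
    d <- df[keep, , drop = FALSE]
    tt <- times[keep]; ee <- events[keep]
    for (j in names(d)) {
      if (is.numeric(d[[j]]) && stats::var(d[[j]]) == 0) {
        stop("zero-variance covariate: ", j)
      }
    }
    fml <- stats::as.formula(paste(
      "survival::Surv(tt, ee) ~", paste(sprintf("`%s`", names(d)), collapse = " + ")))
    fit <- survival::coxph(fml, data = d, ties = "breslow",
                           control = survival::coxph.control(iter.max = 100))
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               lower = s$conf.int[, "lower .95"],
               upper = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               n = s$n, n_event = s$nevent, n_dropped = n_dropped,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (multivariate) {
    fit_one(covariates)
  } else {
    do.call(rbind, lapply(names(covariates), function(j) {
      fit_one(covariates[, j, drop = FALSE])
    }))
  }
}

#' Time-dependent ROC at a fixed horizon
#'
#' Cumulative-case / dynamic-control ROC of a baseline risk score against
#' survival status at horizon `t`, using the Kaplan-Meier-based estimator:
#' within each score stratum defined by a cutoff, the probability of an
#' event by `t` is estimated by the conditional Kaplan-Meier curve, giving
#' censoring-adjusted sensitivity P(score > c | event by t) and
#' specificity P(score <= c | event-free at t). With no censoring before
#' `t` this reduces exactly to the static ROC of the indicator
#' "event by t".
#'
#' @param scores Baseline risk scores (higher = higher risk).
#' @param times,events Survival outcome.
#' @param horizon_t Horizon (same units as `times`).
#' @return An object of class `td_roc`: `horizon`, `auc`, `points`
#'   (cutoff, sensitivity, specificity), `estimator`.
#' @export
time_dependent_roc <- function(scores, times, events, horizon_t) {
  n_case <- sum(times <= horizon_t & events == 1)
  n_ctrl <- sum(times > horizon_t)
  if (n_case == 0) stop("no cases (events by t=", horizon_t, ")")
  if (n_ctrl == 0) stop("no controls (at risk past t=", horizon_t, ")")
  cuts <- roc_cutoffs(scores)
  km_all <- km_estimate(times, events)
  s_t <- km_survival_at(km_all, horizon_t)
  f_t <- 1 - s_t
  sens <- spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    c_ <- cuts[i]
    hi <- scores >= c_
    p_hi <- mean(hi)
    s_hi <- if (any(hi)) cond_surv(times[hi], events[hi], horizon_t) else 1
    s_lo <- if (any(!hi)) cond_surv(times[!hi], events[!hi], horizon_t) else 1
    sens[i] <- if (f_t > 0) (1 - s_hi) * p_hi / f_t else NA_real_
    spec[i] <- if (s_t > 0) s_lo * (1 - p_hi) / s_t else NA_real_
  }
  sens <- pmin(1, pmax(0, sens))
  spec <- pmin(1, pmax(0, spec))
  # sort on rounded keys: product-limit arithmetic leaves ~1e-15 jitter on
  # what are exact ties, which would otherwise scramble the step order
  ord <- order(round(1 - spec, 10), round(sens, 10))
  fpr <- (1 - spec)[ord]; tpr <- sens[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(horizon = horizon_t, auc = auc,
         points = data.frame(cutoff = cuts, sensitivity = sens,
                             specificity = spec),
         estimator = "cumulative/dynamic Kaplan-Meier",
         n_case = n_case, n_control = n_ctrl),
    class = "td_roc"
  )
}

cond_surv <- function(times, events, t) {
  km <- km_estimate(times, events)
  km_survival_at(km, t)
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC at t=%g: AUC %.4f (%d cases, %d controls; %s)\n",
              x$horizon, x$auc, x$n_case, x$n_control, x$estimator))
  invisible(x)
}

#' Horizon classification of a risk score
#'
#' Compares predicted survival status against observed status at each
#' horizon. "Positive" means predicted alive: for a risk-oriented score
#' (higher = higher risk) a sample is predicted alive when its score is
#' below the cutoff. Samples censored before a horizon are excluded at
#' that horizon; if all samples are censored before a horizon it is
#' skipped with a warning.
#'
#' @param scores Risk scores.
#' @param times,events Survival outcome.
#' @param horizons Months at which status is classified (default
#'   c(6, 12, 24)).
#' @param cutoff Score cutoff (e.g. median score or a maxstat cutpoint).
#' @param higher_is_risk Score orientation (default TRUE).
#' @return Data frame with one row per evaluable horizon: `horizon`,
#'   `tp`, `fp`, `tn`, `fn`, `n_excluded`, `sensitivity`, `specificity`,
#'   `accuracy`.
#' @export
horizon_classification <- function(scores, times, events,
                                   horizons = c(6, 12, 24), cutoff,
                                   higher_is_risk = TRUE) {
  pred_alive <- if (higher_is_risk) scores < cutoff else scores >= cutoff
  rows <- lapply(horizons, function(t) {
    excluded <- times < t & events == 0
    if (all(excluded)) {
      warning("all samples censored before horizon ", t, "; skipped")
      return(NULL)
    }
    dead <- events == 1 & times <= t
    alive <- !excluded & !dead
    tp <- sum(pred_alive & alive); fn <- sum(!pred_alive & alive)
    fp <- sum(pred_alive & dead); tn <- sum(!pred_alive & dead)
    data.frame(horizon = t, tp = tp, fp = fp, tn = tn, fn = fn,
               n_excluded = sum(excluded),
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               accuracy = (tp + tn) / (tp + tn + fp + fn))
  })
  do.call(rbind, rows)
}

#' Maximally selected logrank cutpoint
#'
#' Scans all candidate cutoffs of a risk score (midpoints of adjacent
#' distinct values within the configured quantile bounds) and returns the
#' one maximizing the absolute standardized two-sample logrank statistic.
#' The reported logrank p-value is the naive one and is flagged as
#' selection-biased: it does not account for the maximal selection.
#'
#' @param scores Risk scores.
#' @param times,events Survival outcome.
#' @param bounds Quantile bounds for candidate cutoffs (default
#'   c(0.1, 0.9)).
#' @return An object of class `cutpoint_result`: `method`, `cutoff`,
#'   `statistic` (standardized logrank |z| at the cutoff), `p`
#'   (`selection_biased = TRUE`), group sizes, `hr` with CI.
#' @export
best_cutpoint_maxstat <- function(scores, times, events,
                                  bounds = c(0.1, 0.9)) {
  qs <- stats::quantile(scores, bounds)
  if (sum(scores >= qs[1] & scores <= qs[2]) < 10) {
    stop("fewer than 10 samples between the quantile bounds")
  }
  s <- sort(unique(scores))
  mids <- (utils::head(s, -1) + utils::tail(s, -1)) / 2
  cand <- mids[mids >= qs[1] & mids <= qs[2]]
  if (length(cand) < 2) stop("fewer than 2 candidate cutoffs within bounds")
  zs <- vapply(cand, function(c_) {
    g <- scores >= c_
    if (!any(g) || all(g)) return(NA_real_)
    abs(logrank_test(times, events, g)$z)
  }, 0)
  best <- which.max(zs)
  cut_ <- cand[best]
  cutpoint_summary("maxstat", cut_, scores, times, events,
                   statistic = zs[best], selection_biased = TRUE)
}

#' Median risk-score cutpoint
#'
#' Dichotomizes at the median score (ties assigned to the low-score group)
#' and summarizes the two survival curves with the logrank test and a
#' univariate Cox hazard ratio.
#'
#' @inheritParams best_cutpoint_maxstat
#' @return A `cutpoint_result`.
#' @export
median_cutpoint <- function(scores, times, events) {
  cut_ <- stats::median(scores)
  cutpoint_summary("median", cut_, scores, times, events,
                   statistic = NA_real_, selection_biased = FALSE)
}

cutpoint_summary <- function(method, cut_, scores, times, events,
                             statistic, selection_biased) {
  # ties at the cutoff fall in the low-score group
  g <- scores > cut_
  lr <- logrank_test(times, events, g)
  cx <- summary(survival::coxph(
    survival::Surv(times, events) ~ g, ties = "breslow"))
  structure(
    list(method = method, cutoff = cut_,
         statistic = if (is.na(statistic)) sqrt(lr$statistic) else statistic,
         p = lr$p, selection_biased = selection_biased,
         n_low = sum(!g), n_high = sum(g),
         hr = cx$conf.int[1, "exp(coef)"],
         hr_lower = cx$conf.int[1, "lower .95"],
         hr_upper = cx$conf.int[1, "upper .95"]),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    "Cutpoint (%s) at %.4g: %d low / %d high, HR %.2f (%.2f-%.2f), logrank p=%.3g%s\n",
    x$method, x$cutoff, x$n_low, x$n_high, x$hr, x$hr_lower, x$hr_upper, x$p,
    if (x$selection_biased) " [selection-biased]" else ""))
  invisible(x)
}

#' Per-marker Kaplan-Meier screen
#'
#' For every marker, splits a patient subgroup at the marker's median NPX
#' level (ties assigned to the low group) and reports the logrank p-value
#' and hazard ratio of the high-vs-low split, flagging markers at
#' unadjusted p < 0.05. Markers with more than 50% ties at the median are
#' flagged.
#'
#' @param cohort A `cohort_table`.
#' @param subset Logical or sample-id vector selecting the subgroup
#'   (default all samples).
#' @param alpha Flagging level (default 0.05).
#' @return Data frame with one row per marker: `marker`, `median_npx`,
#'   `n_low`, `n_high`, `logrank_p`, `hr`, `flagged`, `tie_flag`.
#' @export
per_marker_km_screen <- function(cohort, subset = NULL, alpha = 0.05) {
  cl <- cohort$clinical
  keep <- if (is.null(subset)) rep(TRUE, nrow(cl))
          else if (is.logical(subset)) subset
          else cl$sample_id %in% subset
  if (sum(keep) < 10) stop("subgroup needs at least 10 samples")
  tt <- cl$os_months[keep]; ee <- cl$event[keep]
  xx <- cohort$npx[keep, , drop = FALSE]
  rows <- lapply(cohort$markers, function(m) {
    v <- xx[, m]
    med <- stats::median(v)
    g <- v > med
    tie_flag <- mean(v == med) > 0.5
    if (!any(g) || all(g)) {
      return(data.frame(marker = m, median_npx = med, n_low = sum(!g),
                        n_high = sum(g), logrank_p = NA_real_,
                        hr = NA_real_, flagged = FALSE, tie_flag = TRUE))
    }
    lr <- logrank_test(tt, ee, g)
    cx <- summary(survival::coxph(survival::Surv(tt, ee) ~ g,
                                  ties = "breslow"))
    data.frame(marker = m, median_npx = med, n_low = sum(!g),
               n_high = sum(g), logrank_p = lr$p,
               hr = cx$conf.int[1, "exp(coef)"],
               flagged = lr$p < alpha, tie_flag = tie_flag)
  })
  do.call(rbind, rows)
}
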