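#' Run the full discovery and evaluation pipeline
#'
#' Convenience driver chaining every stage on one comparison: differential
#' expression, resampled-LASSO stability selection with signature sets and
#' Ridge evaluation, the median-lambda L1 logistic classifier and
#' non-negative L1 Cox risk model, and the survival-evaluation layer
#' (time-dependent ROC, median and maximally selected cutpoints, horizon
#' classification, Cox proportional-hazards summaries). All randomness
#' derives from the seeds carried by the two configuration objects, so a
#' repeated run produces identical result tables.
#'
#' @param cohort A `cohort_table`.
#' @param cfg A `pipeline_config`.
#' @param comparison Name of the catalog comparison to analyze (default
#'   `"resectable_vs_unresectable"`).
#' @param signature_threshold Which signature set to carry into Ridge
#'   evaluation: `"best"` picks the smallest set with at least 2 markers
#'   and threshold >= 0.5, falling back to the highest-threshold
#'   non-trivial set.
#' @return List of result tables: `de`, `volcano`, `proportion_scores`,
#'   `signature_sets`, `signature_evaluation`, `logistic_model`,
#'   `cox_model`, `risk_scores`, `td_roc`, `cutpoints`,
#'   `horizon_classification`, `cox_ph`.
#' @export
run_pipeline <- function(cohort, cfg,
                         comparison = "resectable_vs_unresectable",
                         signature_threshold = "best") {
  catalog <- build_comparison_catalog(cohort)
  spec <- catalog[[comparison]]
  if (is.null(spec)) stop("unknown comparison: ", comparison)

  de <- run_comparison(cohort, spec)
  des <- extract_design(cohort, spec)

  plan <- make_split_plan(des$y, cfg)
  props <- run_stability(des$x, des$y, plan, cfg)
  sets <- build_signature_sets(props, cfg$proportion_step)

  pick <- pick_signature(sets, signature_threshold)
  sig_eval <- evaluate_signature(pick, des$x, des$y, plan, cfg)

  logit <- fit_median_lambda_logistic(des$x, des$y, cfg)

  cl <- cohort$clinical
  cox_model <- fit_median_lambda_cox(cohort$npx, cl$os_months, cl$event,
                                     nonneg = TRUE, cfg = cfg)
  risk <- predict_score(cox_model, cohort$npx)

  tdroc <- lapply(cfg$evaluation_horizons, function(t) {
    tryCatch(time_dependent_roc(risk, cl$os_months, cl$event, t),
             error = function(e) NULL)
  })
  tdroc_tab <- do.call(rbind, lapply(tdroc[!vapply(tdroc, is.null, TRUE)],
    function(r) data.frame(horizon = r$horizon, auc = r$auc,
                           n_case = r$n_case, n_control = r$n_control)))

  med_cut <- median_cutpoint(risk, cl$os_months, cl$event)
  max_cut <- best_cutpoint_maxstat(risk, cl$os_months, cl$event)
  horizon <- horizon_classification(risk, cl$os_months, cl$event,
                                    cfg$evaluation_horizons,
                                    cutoff = med_cut$cutoff)

  covars <- data.frame(age_years = cl$age_years, stage = cl$stage,
                       asa = cl$asa,
                       adjuvant_chemo = factor(cl$adjuvant_chemo),
                       log2_ca199 = log2(cl$ca199_uml),
                       risk_score = risk)
  coxph_tab <- cox_ph(cl$os_months, cl$event, covars, multivariate = FALSE)

  list(
    comparison = comparison,
    de = de$results, volcano = de$volcano,
    proportion_scores = props,
    signature_sets = sets,
    signature_evaluation = sig_eval,
    logistic_model = logit,
    cox_model = cox_model,
    risk_scores = risk,
    td_roc = tdroc_tab,
    cutpoints = list(median = med_cut, maxstat = max_cut),
    horizon_classification = horizon,
    cox_ph = coxph_tab
  )
}

pick_signature <- function(sets, rule) {
  if (inherits(rule, "signature_set")) return(rule)
  sizes <- vapply(sets, function(s) length(s$markers), 0)
  ths <- vapply(sets, `[[`, 0, "threshold")
  ok <- which(sizes >= 2 & ths >= 0.5)
  if (length(ok)) return(sets[[ok[which.min(sizes[ok])]]])
  ok <- which(sizes >= 2)
  sets[[ok[which.max(ths[ok])]]]
}
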