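#' Discovery/replication split plan with resampled half-splits
#'
#' Splits the samples into a discovery and a replication cohort, stratified
#' by class at `discovery_fraction`, and pre-draws one stratified half-split
#' of the discovery cohort per stability iteration (the training/test halves
#' of each resampled LASSO fit). The plan is fully determined by the seed.
#'
#' @param labels 0/1 integer vector (named or not); both classes need at
#'   least 4 members.
#' @param cfg A `pipeline_config`.
#' @param seed Integer seed (defaults to the config's split seed).
#' @return An object of class `split_plan` with `discovery`, `replication`
#'   (integer indices into `labels`) and `halves` (list of
#'   `n_stability_iter` integer vectors: the training half of discovery,
#'   as indices into `labels`).
#' @export
make_split_plan <- function(labels, cfg, seed = derive_seed(cfg$seed, "split")) {
  stopifnot(all(labels %in% 0:1))
  if (min(table(factor(labels, levels = 0:1))) < 4) {
    stop("each class needs at least 4 members")
  }
  set.seed(seed)
  idx0 <- which(labels == 0); idx1 <- which(labels == 1)
  take <- function(idx, frac) {
    n <- round(length(idx) * frac)
    n <- max(1L, min(length(idx) - 1L, n))
    sort(sample(idx, n))
  }
  disc <- sort(c(take(idx0, cfg$discovery_fraction),
                 take(idx1, cfg$discovery_fraction)))
  repl <- sort(setdiff(seq_along(labels), disc))
  halves <- lapply(seq_len(cfg$n_stability_iter), function(i) {
    d0 <- intersect(disc, idx0); d1 <- intersect(disc, idx1)
    sort(c(take(d0, 0.5), take(d1, 0.5)))
  })
  structure(
    list(seed = seed, discovery = disc, replication = repl,
         halves = halves, labels = as.integer(labels)),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "Split plan: discovery n=%d, replication n=%d, %d half-splits (seed %d)\n",
    length(x$discovery), length(x$replication), length(x$halves), x$seed))
  invisible(x)
}

# cv.glmnet warns when folds hold < 3 observations (it switches to
# ungrouped CV); that switch is expected at small training sizes.
quiet_cv <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("grouped=FALSE enforced", conditionMessage(w), fixed = TRUE)) {
      invokeRestart("muffleWarning")
    }
  })
}

nonzero_coefs <- function(fit, s, tol = 1e-10) {
  cf <- as.matrix(stats::coef(fit, s = s))
  cf <- cf[setdiff(rownames(cf), "(Intercept)"), 1]
  abs(cf) > tol
}

#' Resampled-LASSO proportion scores
#'
#' For each pre-drawn half-split of the discovery cohort, fits an
#' L1-penalized logistic model on the training half with the penalty chosen
#' by internal 10-fold cross-validation, and records which markers enter
#' the model with a nonzero coefficient. The per-marker selection frequency
#' across all iterations is the proportion score: markers that persist
#' across resampling are the stable predictors.
#'
#' @param x Marker matrix (samples x markers).
#' @param y 0/1 labels aligned with `x`.
#' @param plan A `split_plan` for these labels.
#' @param cfg A `pipeline_config`.
#' @return An object of class `proportion_score_table`: data frame with
#'   `marker`, `count`, `proportion`; attributes `n_models` and `n_redrawn`.
#' @export
run_stability <- function(x, y, plan, cfg) {
  stopifnot(length(y) == nrow(x), length(plan$labels) == length(y))
  counts <- stats::setNames(rep(0L, ncol(x)), colnames(x))
  set.seed(derive_seed(plan$seed, "stability"))
  n_redrawn <- 0L
  d0 <- intersect(plan$discovery, which(y == 0))
  d1 <- intersect(plan$discovery, which(y == 1))
  for (i in seq_along(plan$halves)) {
    train <- plan$halves[[i]]
    while (length(unique(y[train])) < 2) {   # guard; stratified halves
      n_redrawn <- n_redrawn + 1L
      train <- sort(c(sample(d0, max(1, length(d0) %/% 2)),
                      sample(d1, max(1, length(d1) %/% 2))))
    }
    cv <- quiet_cv(glmnet::cv.glmnet(x[train, , drop = FALSE], y[train],
                                     family = "binomial", alpha = 1,
                                     nfolds = cfg$cv_folds))
    counts <- counts + nonzero_coefs(cv, cv$lambda.min)
  }
  out <- data.frame(marker = colnames(x), count = as.integer(counts),
                    proportion = as.numeric(counts) / length(plan$halves),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_models") <- length(plan$halves)
  attr(out, "n_redrawn") <- n_redrawn
  class(out) <- c("proportion_score_table", "data.frame")
  out
}

#' Build nested signature sets from proportion scores
#'
#' Generates candidate marker sets at thresholds 0, step, 2*step, ..., 1
#' (21 candidates at the default step of 0.05): each set holds the markers
#' whose proportion score is at least the threshold. Identical marker lists
#' are deduplicated keeping only the highest-threshold copy, and empty sets
#' are dropped, so the retained family is strictly nested with strictly
#' decreasing sizes.
#'
#' @param proportions A `proportion_score_table` (or data frame with
#'   `marker` and `proportion`).
#' @param step Threshold increment (default 0.05).
#' @return List of `signature_set` objects, ordered by increasing
#'   threshold; each has `threshold` and `markers`.
#' @export
build_signature_sets <- function(proportions, step = 0.05) {
  thresholds <- round(seq(0, 1, by = step), 10)
  sets <- lapply(thresholds, function(th) {
    proportions$marker[proportions$proportion >= th - 1e-9]
  })
  keep <- logical(length(sets))
  seen <- character()
  for (i in rev(seq_along(sets))) {   # highest threshold wins duplicates
    key <- paste(sort(sets[[i]]), collapse = "\r")
    if (length(sets[[i]]) > 0 && !key %in% seen) {
      keep[i] <- TRUE
      seen <- c(seen, key)
    }
  }
  out <- lapply(which(keep), function(i) {
    structure(list(threshold = thresholds[i], markers = sets[[i]]),
              class = "signature_set")
  })
  out[order(vapply(out, `[[`, 0, "threshold"))]
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature set (threshold %.2f, %d markers): %s\n",
              x$threshold, length(x$markers),
              paste(x$markers, collapse = ", ")))
  invisible(x)
}

# Ridge-logistic fit used for signature evaluation; falls back to an
# unpenalized logistic fit for single-marker sets (the Ridge score is
# monotone in the marker there, so only the ranking matters).
ridge_score <- function(x_train, y_train, x_eval, cv_folds) {
  if (ncol(x_train) == 1) {
    df <- data.frame(y = y_train, v = x_train[, 1])
    fit <- suppressWarnings(
      stats::glm(y ~ v, data = df, family = stats::binomial()))
    return(drop(stats::predict(fit, data.frame(v = x_eval[, 1]))))
  }
  cv <- quiet_cv(glmnet::cv.glmnet(x_train, y_train, family = "binomial",
                                   alpha = 0, nfolds = cv_folds))
  drop(stats::predict(cv, newx = x_eval, s = cv$lambda.min))
}

#' Evaluate a signature set with Ridge regression
#'
#' Two evaluations of one marker set: (i) a Ridge-logistic model fitted on
#' the first training half of the discovery cohort and scored on the other
#' half; (ii) a Ridge-logistic model fitted on the entire discovery cohort
#' and scored on the replication cohort. Each evaluation reports the ROC
#' AUC, the Youden best point with sensitivity, specificity, PPV and NPV,
#' and percentile bootstrap 95% confidence intervals from stratified
#' resampling of the evaluation set (the fitted model held fixed).
#'
#' @param set A `signature_set`.
#' @param x Marker matrix; `y` 0/1 labels; `plan` the `split_plan`.
#' @param y,plan,cfg See above; `cfg` supplies folds and bootstrap count.
#' @param seed Seed for the bootstrap (defaults to the config's).
#' @return List of two `signature_evaluation` objects, named
#'   `"discovery_half"` and `"replication"`.
#' @export
evaluate_signature <- function(set, x, y, plan, cfg,
                               seed = derive_seed(cfg$seed, "bootstrap")) {
  if (!length(set$markers)) stop("signature set is empty")
  xs <- x[, set$markers, drop = FALSE]
  half1 <- plan$halves[[1]]
  half2 <- setdiff(plan$discovery, half1)
  evals <- list(
    discovery_half = list(train = half1, eval = half2),
    replication = list(train = plan$discovery, eval = plan$replication)
  )
  set.seed(seed)
  out <- lapply(names(evals), function(nm) {
    tr <- evals[[nm]]$train; ev <- evals[[nm]]$eval
    if (length(unique(y[ev])) < 2) stop("evaluation set has a single class")
    sc <- ridge_score(xs[tr, , drop = FALSE], y[tr],
                      xs[ev, , drop = FALSE], cfg$cv_folds)
    evaluate_scores(sc, y[ev], n_bootstrap = cfg$n_bootstrap,
                    label = nm, signature = set)
  })
  names(out) <- names(evals)
  out
}

# Shared score-vs-label evaluation: ROC/AUC, Youden point, and stratified
# percentile bootstrap CIs for all five metrics. Bootstrap replicates
# recompute the Youden cutoff, so threshold instability is part of the CI.
evaluate_scores <- function(scores, labels, n_bootstrap, label = "",
                            signature = NULL) {
  roc <- roc_auc(scores, labels)
  best <- youden_best_point(roc)
  metric_fn <- function(s, l) {
    r <- roc_auc(s, l)
    b <- youden_best_point(r)
    c(auc = r$auc, sensitivity = b$sensitivity, specificity = b$specificity,
      ppv = b$ppv, npv = b$npv)
  }
  boot <- bootstrap_ci(metric_fn, scores, labels, n = n_bootstrap)
  structure(
    list(signature = signature, cohort_label = label,
         auc = roc$auc, youden_cutoff = best$cutoff,
         sensitivity = best$sensitivity, specificity = best$specificity,
         ppv = best$ppv, npv = best$npv,
         ci = boot, n = length(labels), roc = roc),
    class = "signature_evaluation"
  )
}

#' @export
print.signature_evaluation <- function(x, ...) {
  ci <- x$ci
  fmt <- function(m) sprintf("%.3f (%.3f-%.3f)", x[[m]], ci[m, 1], ci[m, 2])
  cat(sprintf("Signature evaluation [%s], n=%d\n", x$cohort_label, x$n))
  cat(sprintf("  AUC %s  sens %s  spec %s\n",
              fmt("auc"), fmt("sensitivity"), fmt("specificity")))
  cat(sprintf("  PPV %s  NPV %s  (Youden cutoff %.4g)\n",
              fmt("ppv"), fmt("npv"), x$youden_cutoff))
  invisible(x)
}
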