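#' Standardize a marker matrix
#'
#' Centers each column to mean 0 and scales to unit sample standard
#' deviation (n - 1 convention). The means and SDs are returned so that new
#' samples can be scored on the training scale.
#'
#' @param x Numeric matrix, samples x markers.
#' @return List with `x` (standardized matrix), `center`, `scale`.
#' @export
standardize <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance marker(s): ",
         paste(colnames(x)[scl == 0], collapse = ", "))
  }
  xz <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  list(x = xz, center = ctr, scale = scl)
}

new_fitted_model <- function(family, weights, intercept, lambda,
                             center, scale, weight_dist, lambdas = NULL) {
  structure(
    list(family = family, weights = weights, intercept = intercept,
         lambda = lambda, center = center, scale = scale,
         weight_dist = weight_dist, lambdas = lambdas),
    class = "fitted_linear_model"
  )
}

#' @export
print.fitted_linear_model <- function(x, ...) {
  nz <- sum(abs(x$weights) > 1e-10)
  cat(sprintf("Penalized linear model (%s): lambda=%.5g, %d/%d nonzero weights\n",
              x$family, x$lambda, nz, length(x$weights)))
  if (!is.null(x$intercept)) cat(sprintf("  intercept: %.6g\n", x$intercept))
  w <- x$weights[abs(x$weights) > 1e-10]
  if (length(w)) {
    for (m in names(w)) cat(sprintf("  %-12s %+.6f\n", m, w[m]))
  }
  invisible(x)
}

summarize_weight_dist <- function(wmat) {
  data.frame(
    marker = rownames(wmat),
    median = apply(wmat, 1, stats::median),
    q25 = apply(wmat, 1, stats::quantile, 0.25),
    q75 = apply(wmat, 1, stats::quantile, 0.75),
    selection_fraction = rowMeans(abs(wmat) > 1e-10),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# Repeat cross-validation n_repeats times, collect the deviance-minimizing
# lambda of each repetition, and refit once at the median lambda. Shared by
# the logistic and Cox variants.
median_lambda_fit <- function(x, y_glmnet, family, cfg, seed,
                              n_repeats, lower_limits = -Inf,
                              lambda = NULL) {
  z <- standardize(x)
  fit_args <- list(x = z$x, y = y_glmnet, family = family, alpha = 1,
                   standardize = FALSE, lower.limits = lower_limits)
  if (!is.null(lambda)) {
    fit <- do.call(glmnet::glmnet, fit_args)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE,
                                x = z$x, y = y_glmnet, alpha = 1,
                                family = family, standardize = FALSE,
                                lower.limits = lower_limits,
                                thresh = 1e-13))
    return(list(z = z, lambda = lambda, lambdas = lambda, coefs = cf,
                wmat = NULL))
  }
  set.seed(seed)
  lambdas <- numeric(n_repeats)
  wmat <- matrix(0, nrow = ncol(x), ncol = n_repeats,
                 dimnames = list(colnames(x), NULL))
  for (r in seq_len(n_repeats)) {
    cv <- quiet_cv(do.call(glmnet::cv.glmnet,
                           c(fit_args, list(nfolds = cfg$cv_folds,
                                            type.measure = "deviance"))))
    lambdas[r] <- cv$lambda.min
    cfr <- as.matrix(stats::coef(cv, s = cv$lambda.min))
    wmat[, r] <- cfr[setdiff(rownames(cfr), "(Intercept)"), 1]
  }
  lam <- stats::median(lambdas)
  fit <- do.call(glmnet::glmnet, fit_args)
  cf <- as.matrix(stats::coef(fit, s = lam, exact = TRUE,
                              x = z$x, y = y_glmnet, alpha = 1,
                              family = family, standardize = FALSE,
                              lower.limits = lower_limits,
                              thresh = 1e-13))
  list(z = z, lambda = lam, lambdas = lambdas, coefs = cf, wmat = wmat)
}

#' L1 logistic model with median-of-repeated-CV lambda
#'
#' Standardizes the markers, repeats 10-fold cross-validation
#' `n_repeats` times (each repetition with fresh fold assignments) to
#' obtain a deviance-minimizing penalty per repetition, selects the final
#' penalty as the median of these values, and refits a single LASSO
#' logistic model on all data at that penalty. The distribution of the
#' per-repetition weights is retained as a robustness summary.
#'
#' @param x Marker matrix; `y` 0/1 labels.
#' @param y 0/1 labels.
#' @param cfg A `pipeline_config` (`cv_folds` used; `n_stability_iter`
#'   sets the default number of CV repetitions).
#' @param seed Integer seed for the fold redraws.
#' @param n_repeats Number of CV repetitions (default
#'   `cfg$n_stability_iter`).
#' @param lambda Optional fixed penalty; skips the CV repetitions.
#' @return A `fitted_linear_model` of family `"logistic_l1"` with weights
#'   on the standardized scale.
#' @export
fit_median_lambda_logistic <- function(x, y, cfg,
                                       seed = derive_seed(cfg$seed, "cv"),
                                       n_repeats = cfg$n_stability_iter,
                                       lambda = NULL) {
  stopifnot(all(y %in% 0:1))
  if (min(table(factor(y, levels = 0:1))) < cfg$cv_folds) {
    stop("each class needs at least `cv_folds` members")
  }
  r <- median_lambda_fit(x, y, "binomial", cfg, seed, n_repeats,
                         lambda = lambda)
  w <- r$coefs[setdiff(rownames(r$coefs), "(Intercept)"), 1]
  new_fitted_model("logistic_l1", w, intercept = r$coefs["(Intercept)", 1],
                   lambda = r$lambda, center = r$z$center, scale = r$z$scale,
                   weight_dist = if (is.null(r$wmat)) NULL
                                 else summarize_weight_dist(r$wmat),
                   lambdas = r$lambdas)
}

#' L1 Cox model with median-of-repeated-CV lambda
#'
#' As [fit_median_lambda_logistic()] but maximizing the L1-penalized Cox
#' partial likelihood (Breslow ties) for right-censored survival, with the
#' cross-validated partial-likelihood deviance as the selection criterion.
#' With `nonneg = TRUE` the coefficients are constrained to be
#' non-negative, so only hazard-increasing markers can enter the risk
#' score and truly protective markers are forced to zero.
#'
#' @param x Marker matrix.
#' @param times Positive follow-up times (months).
#' @param events 0/1 event indicators; at least 10 events required.
#' @param nonneg Constrain weights to be >= 0 (default FALSE).
#' @param cfg,seed,n_repeats,lambda As in the logistic variant.
#' @return A `fitted_linear_model` of family `"cox_l1"` or
#'   `"cox_l1_nonneg"`; Cox models carry no intercept.
#' @export
fit_median_lambda_cox <- function(x, times, events, nonneg = FALSE, cfg,
                                  seed = derive_seed(cfg$seed, "cv"),
                                  n_repeats = cfg$n_stability_iter,
                                  lambda = NULL) {
  if (any(times <= 0)) stop("times must be positive")
  if (sum(events) < 10) stop("at least 10 events required")
  y <- survival::Surv(times, events)
  r <- median_lambda_fit(x, y, "cox", cfg, seed, n_repeats,
                         lower_limits = if (nonneg) 0 else -Inf,
                         lambda = lambda)
  w <- r$coefs[, 1]
  names(w) <- rownames(r$coefs)
  new_fitted_model(if (nonneg) "cox_l1_nonneg" else "cox_l1",
                   w, intercept = NULL,
                   lambda = r$lambda, center = r$z$center, scale = r$z$scale,
                   weight_dist = if (is.null(r$wmat)) NULL
                                 else summarize_weight_dist(r$wmat),
                   lambdas = r$lambdas)
}

#' Construct a linear model from known weights
#'
#' Builds a `fitted_linear_model` directly from published or externally
#' estimated weights (already on the standardized scale), for applying an
#' existing signature to new standardized data.
#'
#' @param weights Named numeric vector of marker weights.
#' @param intercept Intercept, or NULL for Cox-type scores.
#' @param family One of `"logistic_l1"`, `"logistic_ridge"`, `"cox_l1"`,
#'   `"cox_l1_nonneg"`.
#' @param center,scale Optional standardization parameters; default
#'   identity (inputs already standardized).
#' @return A `fitted_linear_model`.
#' @export
linear_model_from_weights <- function(weights, intercept = NULL,
                                      family = "logistic_l1",
                                      center = NULL, scale = NULL) {
  stopifnot(family %in% c("logistic_l1", "logistic_ridge",
                          "cox_l1", "cox_l1_nonneg"))
  if (startsWith(family, "cox") && !is.null(intercept)) {
    stop("Cox-family models carry no intercept")
  }
  if (is.null(center)) center <- stats::setNames(rep(0, length(weights)),
                                                 names(weights))
  if (is.null(scale)) scale <- stats::setNames(rep(1, length(weights)),
                                               names(weights))
  new_fitted_model(family, weights, intercept, lambda = NA_real_,
                   center = center, scale = scale, weight_dist = NULL)
}

#' Linear prediction / risk score
#'
#' The per-sample score: the linear combination of standardized marker
#' levels weighted by the model coefficients, plus the intercept for
#' logistic families. For Cox families a higher score means a higher
#' predicted hazard (shorter survival); the orientation is recorded in the
#' `"orientation"` attribute.
#'
#' @param model A `fitted_linear_model`.
#' @param x Marker matrix containing at least the model's marker columns.
#' @return Named numeric vector of scores.
#' @export
predict_score <- function(model, x) {
  mk <- names(model$weights)
  missing <- setdiff(mk, colnames(x))
  if (length(missing)) {
    stop("marker column(s) missing from input: ",
         paste(missing, collapse = ", "))
  }
  xz <- sweep(sweep(x[, mk, drop = FALSE], 2, model$center[mk]),
              2, model$scale[mk], "/")
  sc <- drop(xz %*% model$weights)
  if (!is.null(model$intercept)) sc <- sc + model$intercept
  attr(sc, "orientation") <- if (startsWith(model$family, "cox"))
    "higher_is_risk" else "higher_is_positive_class"
  sc
}
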