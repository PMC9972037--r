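#' Pipeline configuration
#'
#' Bundles the tunable parameters shared by the discovery and evaluation
#' stages: resampling counts, cross-validation folds, bootstrap replicates,
#' the proportion-score grid step, the discovery/replication split fraction
#' and the horizons (in months) at which survival status is classified.
#'
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @param n_stability_iter Number of resampled LASSO fits used for
#'   proportion scores (default 500).
#' @param cv_folds Folds for internal cross-validation (default 10).
#' @param n_bootstrap Bootstrap replicates for confidence intervals
#'   (default 2000).
#' @param proportion_step Grid step for signature-set thresholds
#'   (default 0.05; must divide 1 evenly).
#' @param discovery_fraction Fraction of samples assigned to the discovery
#'   cohort (default 2/3), the remainder forming the replication cohort.
#' @param evaluation_horizons Months at which survival status is
#'   dichotomized for horizon classification (default c(6, 12, 24)).
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            n_stability_iter = 500L,
                            cv_folds = 10L,
                            n_bootstrap = 2000L,
                            proportion_step = 0.05,
                            discovery_fraction = 2 / 3,
                            evaluation_horizons = c(6, 12, 24)) {
  stopifnot(n_stability_iter >= 1, cv_folds >= 2, n_bootstrap >= 1)
  k <- 1 / proportion_step
  if (abs(k - round(k)) > 1e-8) {
    stop("`proportion_step` must divide 1 evenly (e.g. 0.05)")
  }
  if (discovery_fraction <= 0 || discovery_fraction >= 1) {
    stop("`discovery_fraction` must lie strictly between 0 and 1")
  }
  if (any(evaluation_horizons <= 0)) stop("horizons must be positive months")
  structure(
    list(
      seed = as.integer(seed),
      n_stability_iter = as.integer(n_stability_iter),
      cv_folds = as.integer(cv_folds),
      n_bootstrap = as.integer(n_bootstrap),
      proportion_step = proportion_step,
      discovery_fraction = discovery_fraction,
      evaluation_horizons = evaluation_horizons
    ),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  master seed:          %d\n", x$seed))
  cat(sprintf("  stability iterations: %d\n", x$n_stability_iter))
  cat(sprintf("  CV folds:             %d\n", x$cv_folds))
  cat(sprintf("  bootstrap replicates: %d\n", x$n_bootstrap))
  cat(sprintf("  proportion step:      %.2f\n", x$proportion_step))
  cat(sprintf("  discovery fraction:   %.3f\n", x$discovery_fraction))
  cat(sprintf("  horizons (months):    %s\n",
              paste(x$evaluation_horizons, collapse = ", ")))
  invisible(x)
}

# Derive a reproducible stage seed from the master seed. Keeps derived
# seeds inside the 32-bit integer range.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, split = 23L, stability = 37L,
               bootstrap = 53L, cv = 71L, de = 89L)
  off <- offsets[[stage]]
  as.integer((as.double(seed) * 2654435761 + off) %% 2147483647)
}
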