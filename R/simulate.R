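#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Marker levels are
#' correlated Gaussians on the log2 (NPX) scale: a small number of latent
#' factors induce cross-marker correlation, independent noise is added, and
#' informative markers receive a mean shift between the resectable and
#' unresectable groups. Survival is drawn from an exponential
#' (constant-hazard) model calibrated so that each group's uncensored
#' median matches `baseline_median_os`, with per-marker log-hazard effects
#' acting on centered marker values. Right-censoring combines an
#' administrative follow-up horizon with an optional uniform early-censoring
#' fraction.
#'
#' @param n_resectable,n_unresectable Group sizes (defaults 193 and 80).
#' @param n_markers Number of markers including the CA19-9 channel
#'   (default 93).
#' @param n_latent_factors Number of shared latent factors (default 3).
#' @param factor_loading_sd SD of the factor loadings (default 0.5 NPX).
#' @param marker_noise_sd SD of independent marker noise (default 1 NPX).
#' @param resectability_effects Named numeric vector: mean NPX shift of a
#'   marker in the unresectable group relative to the resectable group.
#' @param survival_betas Named numeric vector: Cox log-hazard per NPX unit
#'   (on centered marker values).
#' @param baseline_median_os Length-2 vector, months: median OS of the
#'   resectable and unresectable groups when all survival betas are zero
#'   (defaults 22.6 and 8.2).
#' @param censor_horizon_months Administrative censoring horizon
#'   (default 150, i.e. follow-up closes ~12.5 years after inclusion).
#' @param censor_fraction Fraction of samples subject to an additional
#'   uniform(0, horizon) censoring time (default 0.15).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_resectable = 193L,
                              n_unresectable = 80L,
                              n_markers = 93L,
                              n_latent_factors = 3L,
                              factor_loading_sd = 0.5,
                              marker_noise_sd = 1,
                              resectability_effects = numeric(),
                              survival_betas = numeric(),
                              baseline_median_os = c(resectable = 22.6,
                                                     unresectable = 8.2),
                              censor_horizon_months = 150,
                              censor_fraction = 0.15,
                              seed = 1L) {
  stopifnot(n_resectable >= 2, n_unresectable >= 2, n_markers >= 2,
            n_latent_factors >= 0, factor_loading_sd > 0, marker_noise_sd > 0,
            all(baseline_median_os > 0), censor_horizon_months > 0)
  if (censor_fraction < 0 || censor_fraction >= 1) {
    stop("`censor_fraction` must lie in [0, 1)")
  }
  structure(
    list(
      n_resectable = as.integer(n_resectable),
      n_unresectable = as.integer(n_unresectable),
      n_markers = as.integer(n_markers),
      n_latent_factors = as.integer(n_latent_factors),
      factor_loading_sd = factor_loading_sd,
      marker_noise_sd = marker_noise_sd,
      resectability_effects = resectability_effects,
      survival_betas = survival_betas,
      baseline_median_os = baseline_median_os,
      censor_horizon_months = censor_horizon_months,
      censor_fraction = censor_fraction,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Marker names used by the simulator
#'
#' `n - 1` protein channels `P001, P002, ...` plus the CA19-9 channel.
#' @param n Total number of markers.
#' @export
simulated_marker_names <- function(n) {
  c(sprintf("P%03d", seq_len(n - 1)), "CA19-9")
}

#' Default ground-truth scenario
#'
#' The reference test scenario: five resectability-informative markers with
#' a +1.0 NPX shift in the unresectable group, and five survival-informative
#' markers with log-hazard coefficients of absolute size 0.5 per NPX unit
#' (four hazardous, one protective); all other markers are null.
#'
#' @param seed Seed stored in the configuration.
#' @param ... Further arguments passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_scenario <- function(seed = 1L, ...) {
  res_eff <- rep(1.0, 5)
  names(res_eff) <- sprintf("P%03d", 1:5)
  surv_b <- c(0.5, 0.5, 0.5, 0.5, -0.5)
  names(surv_b) <- sprintf("P%03d", 6:10)
  simulation_config(resectability_effects = res_eff,
                    survival_betas = surv_b, seed = seed, ...)
}

#' Simulate a cohort with known ground truth
#'
#' Draws marker levels, clinical covariates and right-censored survival
#' according to the configuration, and returns both the cohort and the
#' ground truth (informative markers, survival coefficients, latent event
#' times) needed to verify downstream recovery.
#'
#' @param cfg A `simulation_config`.
#' @return List with elements `cohort` (a `cohort_table`) and `truth`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  markers <- simulated_marker_names(cfg$n_markers)
  for (nm in list(cfg$resectability_effects, cfg$survival_betas)) {
    unknown <- setdiff(names(nm), markers)
    if (length(unknown)) {
      stop("effects reference unknown markers: ",
           paste(unknown, collapse = ", "))
    }
  }
  set.seed(cfg$seed)
  n <- cfg$n_resectable + cfg$n_unresectable
  resectable <- rep(c(TRUE, FALSE), c(cfg$n_resectable, cfg$n_unresectable))
  p <- cfg$n_markers

  # baseline marker means: NPX panels sit at a few log2 units; CA19-9 around
  # log2(37 U/ml) so the conventional elevation threshold is mid-scale
  mu <- stats::rnorm(p, mean = 4, sd = 1)
  mu[p] <- log2(37)

  loadings <- matrix(stats::rnorm(p * cfg$n_latent_factors,
                                  sd = cfg$factor_loading_sd),
                     nrow = p)
  factors <- matrix(stats::rnorm(n * cfg$n_latent_factors), nrow = n)
  npx <- matrix(rep(mu, each = n), nrow = n) +
    factors %*% t(loadings) +
    matrix(stats::rnorm(n * p, sd = cfg$marker_noise_sd), nrow = n)
  colnames(npx) <- markers
  rownames(npx) <- sprintf("S%04d", seq_len(n))

  if (length(cfg$resectability_effects)) {
    for (m in names(cfg$resectability_effects)) {
      npx[!resectable, m] <- npx[!resectable, m] + cfg$resectability_effects[[m]]
    }
  }

  # exponential event times: hazard log(2)/median per group, multiplied by
  # exp(beta' x) on centered markers
  lp <- rep(0, n)
  if (length(cfg$survival_betas)) {
    xb <- npx[, names(cfg$survival_betas), drop = FALSE]
    xb <- sweep(xb, 2, colMeans(xb))
    lp <- drop(xb %*% cfg$survival_betas)
  }
  base_med <- ifelse(resectable,
                     cfg$baseline_median_os[[1]], cfg$baseline_median_os[[2]])
  hazard <- log(2) / base_med * exp(lp)
  latent_t <- stats::rexp(n, rate = hazard)

  censor_t <- rep(cfg$censor_horizon_months, n)
  early <- stats::runif(n) < cfg$censor_fraction
  censor_t[early] <- stats::runif(sum(early), 0, cfg$censor_horizon_months)
  os <- pmin(latent_t, censor_t)
  event <- as.integer(latent_t <= censor_t)

  age <- round(pmin(90, pmax(40, stats::rnorm(n, 68, 9))), 1)
  stage <- ifelse(resectable,
                  sample(1:4, n, replace = TRUE, prob = c(0.25, 0.45, 0.25, 0.05)),
                  sample(1:4, n, replace = TRUE, prob = c(0.02, 0.08, 0.40, 0.50)))
  asa <- sample(1:4, n, replace = TRUE, prob = c(0.15, 0.5, 0.3, 0.05))
  asa[sample.int(n, 1)] <- NA  # mirror the occasional missing ASA record
  chemo <- sample(c("none", "gemcitabine", "combination"), n,
                  replace = TRUE, prob = c(0.35, 0.4, 0.25))

  clinical <- data.frame(
    sample_id = rownames(npx),
    resectable = resectable,
    os_months = os,
    event = event,
    age_years = age,
    stage = stage,
    asa = asa,
    adjuvant_chemo = chemo,
    ca199_uml = 2^npx[, "CA19-9"],
    stringsAsFactors = FALSE
  )

  truth <- list(
    resectability_markers = names(cfg$resectability_effects),
    survival_betas = cfg$survival_betas,
    latent_event_times = stats::setNames(latent_t, rownames(npx)),
    factor_loadings = structure(loadings, dimnames = list(markers, NULL))
  )
  list(cohort = cohort_table(npx, clinical), truth = truth)
}

#' Simulate a null cohort
#'
#' Identical to [simulate_cohort()] with all effect maps emptied: labels and
#' survival carry no marker signal. Used as the type-I-error harness.
#'
#' @param cfg A `simulation_config`.
#' @return A `cohort_table`.
#' @export
null_cohort <- function(cfg) {
  cfg$resectability_effects <- numeric()
  cfg$survival_betas <- numeric()
  simulate_cohort(cfg)$cohort
}
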