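# Shared fixtures, all generated in code.

# A tiny hand-checkable cohort (4 samples, 3 markers incl. CA19-9).
tiny_cohort <- function() {
  npx <- matrix(c(1, 2, 3, 4,
                  5, 6, 7, 8,
                  log2(c(10, 37, 74, 200))),
                nrow = 4,
                dimnames = list(paste0("S", 1:4), c("PA", "PB", "CA19-9")))
  clinical <- data.frame(
    sample_id = paste0("S", 1:4),
    resectable = c(TRUE, TRUE, FALSE, FALSE),
    os_months = c(30, 10, 8, 4),
    event = c(0, 1, 1, 1),
    age_years = c(60, 70, 65, 72),
    stage = c(1, 2, 3, 4),
    asa = c(2, 2, 3, NA),
    adjuvant_chemo = c("none", "gemcitabine", "none", "none"),
    ca199_uml = c(10, 37, 74, 200),
    stringsAsFactors = FALSE
  )
  cohort_table(npx, clinical)
}

# Write the tiny cohort's source files into a temp dir (raw CA19-9 U/ml).
tiny_cohort_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  co <- tiny_cohort()
  mp <- file.path(dir, "markers.csv")
  cp <- file.path(dir, "clinical.csv")
  write_cohort(co, mp, cp, digits = 10)
  list(marker = mp, clinical = cp)
}

# A fast small-scale scenario used where the full 273-sample default would
# be wasteful: same structure, reduced n.
small_scenario <- function(seed = 1L, ...) {
  default_scenario(seed = seed, n_resectable = 60L, n_unresectable = 40L, ...)
}

fast_config <- function(seed = 1L, n_stability_iter = 15L,
                        n_bootstrap = 200L, ...) {
  pipeline_config(seed = seed, n_stability_iter = n_stability_iter,
                  n_bootstrap = n_bootstrap, ...)
}
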