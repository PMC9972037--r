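#' Two-group comparison specifications
#'
#' A `comparison_spec` names a two-group contrast over a cohort: either the
#' resectable/unresectable split or a survival dichotomization. Group
#' membership is resolved against the cohort when the catalog is built, so
#' downstream stages operate on explicit sample-id lists.
#'
#' Survival dichotomization under right-censoring follows one rule
#' throughout: a sample censored before the defining threshold is excluded
#' from the comparison (its class is unknowable), while a sample observed
#' past the threshold counts as a long-term survivor regardless of later
#' censoring. Deaths before the threshold are short-term survivors.
#'
#' @name comparison_spec
NULL

new_comparison_spec <- function(name, group1, group2, positive_label,
                                group1_name, group2_name, threshold = NA_real_) {
  usable <- length(group1) >= 2 && length(group2) >= 2
  structure(
    list(
      name = name,
      group1 = group1, group2 = group2,
      group1_name = group1_name, group2_name = group2_name,
      positive_label = positive_label,
      threshold_months = threshold,
      usable = usable
    ),
    class = "comparison_spec"
  )
}

#' @export
print.comparison_spec <- function(x, ...) {
  cat(sprintf("Comparison '%s': %s (n=%d) vs %s (n=%d)%s\n",
              x$name, x$group1_name, length(x$group1),
              x$group2_name, length(x$group2),
              if (x$usable) "" else "  [UNUSABLE]"))
  invisible(x)
}

# Membership for an OS threshold split (months). Short arm = observed death
# before the threshold; long arm = followed past the threshold; censored
# before the threshold = excluded.
split_by_os <- function(clinical, threshold) {
  if (is.na(threshold) || !nrow(clinical)) {
    return(list(short = character(), long = character()))
  }
  short <- clinical$sample_id[which(clinical$os_months < threshold &
                                      clinical$event == 1)]
  long <- clinical$sample_id[which(clinical$os_months >= threshold)]
  list(short = short, long = long)
}

#' Build the standard comparison catalog
#'
#' Returns the seven contrasts the pipeline screens: resectable vs
#' unresectable; within resectable patients, short (<1 year observed death)
#' versus long survival at the 1-, 3-, 4- and 5-year thresholds; and
#' below- versus above-median OS within the unresectable and resectable
#' subgroups, the median computed from each subgroup's observed OS. The
#' poor-outcome arm (unresectable, or short survival) is always the
#' ROC-positive label.
#'
#' @param cohort A `cohort_table`.
#' @return List of 7 `comparison_spec` objects; a comparison whose arms
#'   have fewer than 2 members each is included but flagged unusable.
#' @export
build_comparison_catalog <- function(cohort) {
  cl <- cohort$clinical
  res <- cl[cl$resectable, , drop = FALSE]
  unres <- cl[!cl$resectable, , drop = FALSE]

  specs <- list(
    new_comparison_spec(
      "resectable_vs_unresectable",
      group1 = res$sample_id, group2 = unres$sample_id,
      positive_label = "group2",
      group1_name = "resectable", group2_name = "unresectable"
    )
  )

  for (yrs in c(1, 3, 4, 5)) {
    thr <- 12 * yrs
    arms <- split_by_os(res, 12)      # short arm is always OS < 1 year
    long <- split_by_os(res, thr)$long
    specs <- c(specs, list(new_comparison_spec(
      sprintf("resectable_os_lt1y_vs_gt%dy", yrs),
      group1 = arms$short, group2 = long,
      positive_label = "group1",
      group1_name = "OS < 1 year", group2_name = sprintf("OS > %d years", yrs),
      threshold = thr
    )))
  }

  for (grp in list(list(d = unres, tag = "unresectable"),
                   list(d = res, tag = "resectable"))) {
    med <- if (nrow(grp$d)) stats::median(grp$d$os_months) else NA_real_
    arms <- split_by_os(grp$d, med)
    specs <- c(specs, list(new_comparison_spec(
      sprintf("%s_os_below_vs_above_median", grp$tag),
      group1 = arms$short, group2 = arms$long,
      positive_label = "group1",
      group1_name = "OS < median", group2_name = "OS > median",
      threshold = med
    )))
  }

  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}
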