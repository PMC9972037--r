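#' Choose the two-group test for a marker
#'
#' Large-sample contrasts (both groups of at least 40) use the t-test on
#' central-limit grounds. For smaller groups, normality of each group is
#' checked with the Shapiro-Wilk test: if either group departs from
#' normality at `alpha_normality`, the Wilcoxon rank-sum test is used
#' instead, otherwise the t-test.
#'
#' @param values1,values2 Numeric vectors (log2 NPX), each of length >= 3.
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @return `"t"` or `"wilcoxon"`.
#' @export
choose_test <- function(values1, values2, alpha_normality = 0.05) {
  n1 <- length(values1); n2 <- length(values2)
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 samples")
  if (n1 >= 40 && n2 >= 40) return("t")
  p1 <- stats::shapiro.test(values1)$p.value
  p2 <- stats::shapiro.test(values2)$p.value
  if (p1 < alpha_normality || p2 < alpha_normality) "wilcoxon" else "t"
}

# Wilcoxon rank-sum, two-sided: exact enumeration for small untied groups,
# normal approximation with continuity correction otherwise.
wilcoxon_p <- function(values1, values2) {
  exact <- length(values1) <= 25 && length(values2) <= 25 &&
    !any(duplicated(c(values1, values2)))
  stats::wilcox.test(values1, values2, exact = exact, correct = TRUE)$p.value
}

#' Test one marker between two groups
#'
#' Routes through [choose_test()] and reports the two-sided p-value together
#' with the linear-scale fold change: the ratio of the two groups' geometric
#' means, which on log2 data is `2^(mean1 - mean2)`.
#'
#' @param values1,values2 Numeric vectors of log2 marker levels.
#' @param alpha_normality Passed to [choose_test()].
#' @return List with `p_raw`, `fold_change_linear`, `test_used`,
#'   `mean1`, `mean2`, `n1`, `n2`.
#' @export
compare_marker <- function(values1, values2, alpha_normality = 0.05) {
  n1 <- length(values1); n2 <- length(values2)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  m1 <- mean(values1); m2 <- mean(values2)
  out <- list(p_raw = NA_real_, fold_change_linear = 2^(m1 - m2),
              test_used = NA_character_, mean1 = m1, mean2 = m2,
              n1 = n1, n2 = n2)
  if (stats::sd(values1) == 0 && stats::sd(values2) == 0) {
    # two constant groups: no test needed
    out$p_raw <- if (m1 == m2) 1 else 0
    out$test_used <- "t"
    return(out)
  }
  # groups too small for the Shapiro-based routing fall back to the
  # rank-sum test, which needs no distributional check
  out$test_used <- if (n1 < 3 || n2 < 3) "wilcoxon"
                   else choose_test(values1, values2, alpha_normality)
  out$p_raw <- if (out$test_used == "t") {
    stats::t.test(values1, values2)$p.value
  } else {
    wilcoxon_p(values1, values2)
  }
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, clipped at 1 and returned in
#' the input order.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Run a differential-expression comparison
#'
#' Tests every marker between the two arms of a comparison, applies
#' Benjamini-Hochberg correction across the markers of this comparison,
#' and returns the per-marker results together with a plot-ready volcano
#' table (log2 fold change against -log10 raw p).
#'
#' @param cohort A `cohort_table`.
#' @param spec A usable `comparison_spec`.
#' @param alpha Significance level for the flags (default 0.05).
#' @param alpha_normality Passed to [choose_test()].
#' @return List with `results` and `volcano` data frames, one row per
#'   marker.
#' @export
run_comparison <- function(cohort, spec, alpha = 0.05, alpha_normality = 0.05) {
  des <- extract_design(cohort, spec)
  g1 <- des$x[names(des$y)[des$y == 1], , drop = FALSE]
  g2 <- des$x[names(des$y)[des$y == 0], , drop = FALSE]
  res <- lapply(cohort$markers, function(m) {
    v1 <- g1[, m]; v2 <- g2[, m]
    if (any(is.na(c(v1, v2)))) stop("missing NPX values in marker ", m)
    r <- tryCatch(compare_marker(v1, v2, alpha_normality),
                  error = function(e) stop("marker ", m, ": ",
                                           conditionMessage(e)))
    data.frame(marker = m, test_used = r$test_used,
               n1 = r$n1, n2 = r$n2, mean1 = r$mean1, mean2 = r$mean2,
               fold_change_linear = r$fold_change_linear,
               p_raw = r$p_raw, stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  results$p_adjusted <- bh_adjust(results$p_raw)
  volcano <- data.frame(
    marker = results$marker,
    log2_fold_change = log2(results$fold_change_linear),
    neg_log10_p = -log10(results$p_raw),
    p_adjusted = results$p_adjusted,
    significant_raw = results$p_raw < alpha,
    significant_adjusted = results$p_adjusted < alpha,
    stringsAsFactors = FALSE
  )
  list(results = results, volcano = volcano)
}

#' Principal-component scores of a cohort
#'
#' Exploratory PCA of the full NPX matrix on centered, unit-scaled markers
#' (NPX scales differ per assay, so correlation-scale PCA is used).
#'
#' @param cohort A `cohort_table`.
#' @param k Number of components (default 2).
#' @param scale. Scale markers to unit variance (default TRUE).
#' @return List with `scores` (samples x k), `explained_variance`
#'   (fractions, non-increasing) and the `prcomp` rotation.
#' @export
pca_scores <- function(cohort, k = 2, scale. = TRUE) {
  x <- cohort$npx
  if (k > min(dim(x))) stop("k exceeds min(n_samples, n_markers)")
  sds <- apply(x, 2, stats::sd)
  if (scale. && any(sds == 0)) {
    stop("constant marker(s) cannot be scaled: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)],
       rotation = pc$rotation[, seq_len(k), drop = FALSE])
}
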