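test_that("AUC equals brute-force pair counting, including ties", {
  set.seed(40)
  for (i in 1:5) {
    scores <- round(rnorm(20), 1)   # rounding forces ties
    labels <- rbinom(20, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-9)
  }
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3))$auc, 1.0)
  expect_error(roc_auc(1:5, rep(1, 5)), "both classes")
})

test_that("the ROC curve is a monotone step function from (0,0) to (1,1)", {
  set.seed(41)
  r <- roc_auc(rnorm(30), rbinom(30, 1, 0.4))
  pts <- r$points[order(1 - r$points$specificity, r$points$sensitivity), ]
  fpr <- 1 - pts$specificity
  expect_true(all(diff(fpr) >= -1e-12))
  expect_true(all(diff(pts$sensitivity) >= -1e-12))
  expect_equal(range(fpr), c(0, 1))
  expect_equal(range(pts$sensitivity), c(0, 1))
})

test_that("AUC of a negated score is the complement", {
  set.seed(42)
  scores <- rnorm(25); labels <- rbinom(25, 1, 0.5)
  labels[1:2] <- c(0, 1)
  expect_equal(roc_auc(scores, labels)$auc + roc_auc(-scores, labels)$auc, 1)
})

test_that("Youden best point agrees with the exhaustive oracle", {
  set.seed(43)
  for (i in 1:5) {
    scores <- round(rnorm(30), 1)
    labels <- rbinom(30, 1, 0.5)
    labels[1:2] <- c(0, 1)
    r <- roc_auc(scores, labels)
    best <- youden_best_point(r)
    orc <- oracle_youden(scores, labels)
    expect_equal(best$cutoff, orc$cutoff)
    expect_equal(best$sensitivity, orc$sens)
    expect_equal(best$specificity, orc$spec)
  }
  # perfect separation: J = 1; identical distributions: J = 0
  perf <- roc_auc(c(1, 2, 3, 7, 8, 9), rep(0:1, each = 3))
  expect_equal(youden_best_point(perf)$youden_j, 1)
  same <- roc_auc(c(1, 2, 1, 2), c(0, 0, 1, 1))
  expect_equal(youden_best_point(same)$youden_j, 0)
})

test_that("ROC and Youden agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  scores <- rnorm(60); labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  r <- roc_auc(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  best <- youden_best_point(r)
  co <- pROC::coords(pr, "best", best.method = "youden",
                     ret = c("threshold", "sensitivity", "specificity"))
  expect_equal(best$sensitivity + best$specificity,
               co$sensitivity + co$specificity, tolerance = 1e-9)
})

test_that("stratified bootstrap intervals are deterministic and sane", {
  set.seed(45)
  scores <- c(rnorm(30), rnorm(30, 3)); labels <- rep(0:1, each = 30)
  f <- function(s, l) roc_auc(s, l)$auc
  ci1 <- bootstrap_ci(f, scores, labels, n = 200, seed = 9)
  ci2 <- bootstrap_ci(f, scores, labels, n = 200, seed = 9)
  expect_identical(ci1, ci2)
  # perfectly separated data: the AUC is constant under resampling
  perf <- c(1:10, 101:110); pl <- rep(0:1, each = 10)
  expect_equal(unname(bootstrap_ci(f, perf, pl, n = 100)[1, ]), c(1, 1))
  expect_error(bootstrap_ci(f, scores, labels, n = 50), "100")
})

test_that("null AUC bootstrap intervals cover 0.5 at the nominal rate", {
  cover <- vapply(1:60, function(seed) {
    set.seed(1000 + seed)
    scores <- rnorm(60); labels <- rep(0:1, each = 30)
    ci <- bootstrap_ci(function(s, l) roc_auc(s, l)$auc,
                       scores, labels, n = 200)
    ci[1, "lower"] <= 0.5 && 0.5 <= ci[1, "upper"]
  }, TRUE)
  expect_gte(mean(cover), 0.88)
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  expect_equal(km_survival_at(km, c(0.5, 1, 1.5, 2.7, 5)),
               c(1, 2 / 3, 2 / 3, 1 / 3, 0))
  # all censored: survival stays 1
  km2 <- km_estimate(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(km2$survival == 1))
  # no censoring: equals the empirical survival function
  set.seed(46)
  tt <- rexp(40)
  km3 <- km_estimate(tt, rep(1, 40))
  for (t in quantile(tt, c(0.2, 0.5, 0.8))) {
    expect_equal(km_survival_at(km3, t), oracle_ecdf_surv(tt, t))
  }
  expect_error(km_estimate(numeric(), numeric()), "empty")
})

test_that("the logrank test matches the hand O-E/V computation", {
  set.seed(47)
  tt <- c(rexp(6, 0.2), rexp(6, 0.6)); ee <- rbinom(12, 1, 0.8)
  ee[1] <- 1
  gg <- rep(0:1, each = 6)
  lr <- logrank_test(tt, ee, gg)
  orc <- oracle_logrank(tt, ee, gg)
  expect_equal(lr$statistic, orc$chisq, tolerance = 1e-9)
  expect_equal(abs(lr$z), abs(orc$z), tolerance = 1e-9)
  expect_equal(lr$p, pchisq(orc$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-9)
  # identical groups: statistic 0, p 1 (interleave two copies of one arm)
  t2 <- rep(c(1, 2, 3, 4), 2); e2 <- rep(1, 8); g2 <- rep(0:1, each = 4)
  lr2 <- logrank_test(t2, e2, g2)
  expect_equal(lr2$statistic, 0, tolerance = 1e-12)
  expect_equal(lr2$p, 1, tolerance = 1e-12)
  expect_error(logrank_test(tt, ee, rep(1, 12)), "two")
})

test_that("the logrank statistic is invariant under monotone time maps", {
  set.seed(48)
  tt <- rexp(30) + 0.1; ee <- rbinom(30, 1, 0.7); gg <- rep(0:1, 15)
  a <- logrank_test(tt, ee, gg)$statistic
  b <- logrank_test(log(tt + 1), ee, gg)$statistic
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("Cox regression recovers a planted hazard ratio", {
  hrs <- vapply(1:10, function(seed) {
    set.seed(1100 + seed)
    g <- rbinom(500, 1, 0.5)
    tt <- rexp(500, 0.1 * exp(log(2) * g))
    res <- cox_ph(tt, rep(1, 500), data.frame(g = g))
    res$hr
  }, 0)
  expect_true(all(hrs > 1.6 & hrs < 2.5))
  expect_lt(abs(mean(hrs) - 2), 0.15)
})

test_that("Cox output is structurally sound in both modes", {
  set.seed(49)
  n <- 80
  covs <- data.frame(age = rnorm(n, 65, 8), stage = sample(1:4, n, TRUE),
                     chemo = factor(sample(c("none", "gem"), n, TRUE)))
  tt <- rexp(n, 0.05 * exp(0.03 * (covs$age - 65)))
  ee <- rbinom(n, 1, 0.8); ee[1:10] <- 1
  uni <- cox_ph(tt, ee, covs)
  expect_equal(nrow(uni), 3)
  multi <- cox_ph(tt, ee, covs, multivariate = TRUE)
  expect_equal(nrow(multi), 3)
  expect_true(all(multi$lower <= multi$hr & multi$hr <= multi$upper))
  # missing covariates are dropped and counted
  covs$age[3] <- NA
  uni2 <- cox_ph(tt, ee, covs)
  expect_equal(uni2$n_dropped[uni2$term == "age"], 1)
  covs$flat <- 1
  expect_error(cox_ph(tt, ee, covs["flat"]), "flat")
})

test_that("Cox score test equals the logrank statistic for a binary split", {
  set.seed(50)
  tt <- rexp(40, 0.2); ee <- rbinom(40, 1, 0.8); g <- rep(0:1, 20)
  ee[1:2] <- 1
  sc <- survival::coxph(survival::Surv(tt, ee) ~ g,
                        ties = "breslow")$score
  lr <- logrank_test(tt, ee, g)$statistic
  expect_equal(sc, lr, tolerance = 1e-6)
})

test_that("time-dependent ROC reduces exactly to static ROC when uncensored", {
  set.seed(51)
  n <- 60
  scores <- rnorm(n)
  tt <- rexp(n, 0.1 * exp(0.5 * scores))
  horizon <- median(tt)
  td <- time_dependent_roc(scores, tt, rep(1, n), horizon)
  static <- roc_auc(scores, as.integer(tt <= horizon))
  expect_equal(td$auc, static$auc, tolerance = 1e-12)
  # perfect ranking: score = -(event time)
  td2 <- time_dependent_roc(-tt, tt, rep(1, n), horizon)
  expect_equal(td2$auc, 1)
})

test_that("time-dependent ROC handles censoring and degenerate horizons", {
  set.seed(52)
  n <- 273
  scores <- rnorm(n)
  tt <- rexp(n, 1 / 20)
  cc <- runif(n, 0, 60)
  obs <- pmin(tt, cc); ee <- as.integer(tt <= cc)
  td <- time_dependent_roc(scores, obs, ee, 12)
  expect_gt(td$auc, 0.40); expect_lt(td$auc, 0.60)
  expect_true(td$n_case >= 1 && td$n_control >= 1)
  expect_error(time_dependent_roc(scores, obs + 100, ee, 12), "no cases")
  expect_error(time_dependent_roc(scores, obs / 1000, ee, 12), "no controls")
})

test_that("horizon classification matches per-sample enumeration", {
  set.seed(53)
  n <- 50
  scores <- rnorm(n)
  tt <- rexp(n, 1 / 15); ee <- rbinom(n, 1, 0.7)
  cut_ <- median(scores)
  tab <- horizon_classification(scores, tt, ee, horizons = c(6, 12, 24),
                                cutoff = cut_)
  for (i in seq_len(nrow(tab))) {
    orc <- oracle_horizon(scores, tt, ee, tab$horizon[i], cut_)
    expect_equal(unlist(tab[i, c("tp", "fp", "tn", "fn", "n_excluded")],
                        use.names = FALSE),
                 unname(orc))
  }
  # flipping the orientation complements the predictions
  flip <- horizon_classification(-scores, tt, ee, horizons = 12,
                                 cutoff = -cut_, higher_is_risk = FALSE)
  base <- tab[tab$horizon == 12, ]
  expect_equal(flip$tp + flip$fn, base$tp + base$fn)
  # all predicted alive and all alive: sensitivity 1
  tab2 <- horizon_classification(rep(-1, 10), rep(100, 10), rep(0, 10),
                                 horizons = 6, cutoff = 0)
  expect_equal(tab2$sensitivity, 1)
  expect_equal(tab2$fn, 0)
})

test_that("the maxstat cutpoint matches an exhaustive independent scan", {
  set.seed(54)
  for (i in 1:3) {
    n <- 30
    scores <- rnorm(n)
    tt <- rexp(n, 0.1 * exp(0.8 * (scores > 0)))
    ee <- rbinom(n, 1, 0.85); ee[1:3] <- 1
    cp <- best_cutpoint_maxstat(scores, tt, ee)
    orc <- oracle_maxstat(scores, tt, ee)
    expect_equal(cp$cutoff, orc$cutoff, tolerance = 1e-9)
    expect_equal(cp$statistic, orc$z, tolerance = 1e-9)
    qs <- quantile(scores, c(0.1, 0.9))
    expect_gte(cp$cutoff, qs[[1]]); expect_lte(cp$cutoff, qs[[2]])
    expect_true(cp$selection_biased)
  }
})

test_that("maxstat recovers a planted median changepoint", {
  hit <- vapply(1:10, function(seed) {
    set.seed(1200 + seed)
    n <- 300
    scores <- rnorm(n)
    thr <- quantile(scores, 0.5)
    tt <- rexp(n, 0.05 * exp(log(3) * (scores > thr)))
    cc <- runif(n, 0, quantile(tt, 0.95) * 2)
    cp <- best_cutpoint_maxstat(pmin(scores, 1e9), pmin(tt, cc),
                                as.integer(tt <= cc))
    abs(mean(scores < cp$cutoff) - 0.5) <= 0.10
  }, TRUE)
  expect_gte(mean(hit), 0.9)
})

test_that("median cutpoints dichotomize with ties in the low group", {
  set.seed(55)
  scores <- c(rep(1, 6), 2, 3, 4, 5)
  tt <- rexp(10, 0.2); ee <- rep(1, 10)
  mc <- median_cutpoint(scores, tt, ee)
  expect_equal(mc$method, "median")
  expect_equal(mc$n_low, sum(scores <= mc$cutoff))
  expect_false(mc$selection_biased)
})

test_that("the per-marker KM screen flags planted survival markers", {
  cfg <- small_scenario(seed = 61)
  co <- simulate_cohort(cfg)$cohort
  screen <- per_marker_km_screen(co)
  expect_equal(nrow(screen), 93)
  expect_true(all(screen$n_low + screen$n_high == n_samples(co)))
  # P006-P009 carry beta = +0.5/NPX; at least some should be flagged
  hits <- screen$flagged[screen$marker %in% sprintf("P%03d", 6:9)]
  expect_gte(sum(hits), 2)
})

test_that("the null KM screen flags markers at roughly the nominal rate", {
  flagged <- vapply(1:15, function(seed) {
    co <- null_cohort(small_scenario(seed = 1300 + seed))
    sum(per_marker_km_screen(co)$flagged)
  }, 0)
  expect_gte(mean(flagged), 2.0)
  expect_lte(mean(flagged), 8.5)
})
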