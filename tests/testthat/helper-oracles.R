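# Independent brute-force oracles used to validate the implementations.
# These stay deliberately naive (pair counting, exhaustive scans, direct
# risk-set bookkeeping) and share no code with the package.

# AUC by pair counting: (concordant + half ties) / (n1 * n0).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive Youden scan over all midpoint cutoffs (positive = score >= c),
# with the package's tie rule re-stated independently.
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cuts <- c(-Inf, (head(s, -1) + tail(s, -1)) / 2, Inf)
  best <- NULL
  for (c_ in cuts) {
    sens <- mean(scores[labels == 1] >= c_)
    spec <- mean(scores[labels == 0] < c_)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
         (spec > best$spec + 1e-12 ||
          (abs(spec - best$spec) <= 1e-12 && c_ > best$cutoff)))) {
      best <- list(cutoff = c_, sens = sens, spec = spec, j = j)
    }
  }
  best
}

# Logrank O, E, V from first principles: walk the distinct event times and
# accumulate hypergeometric moments for group 1.
oracle_logrank <- function(times, events, group) {
  g <- as.integer(factor(group)) - 1L   # 0/1
  ts <- sort(unique(times[events == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O = O, E = E, V = V, chisq = (O - E)^2 / V,
       z = (O - E) / sqrt(V))
}

# Exhaustive maxstat scan using the oracle logrank.
oracle_maxstat <- function(scores, times, events, bounds = c(0.1, 0.9)) {
  qs <- quantile(scores, bounds)
  s <- sort(unique(scores))
  mids <- (head(s, -1) + tail(s, -1)) / 2
  cand <- mids[mids >= qs[1] & mids <= qs[2]]
  zs <- sapply(cand, function(c_) {
    g <- scores >= c_
    if (!any(g) || all(g)) return(NA)
    abs(oracle_logrank(times, events, g)$z)
  })
  list(cutoff = cand[which.max(zs)], z = max(zs, na.rm = TRUE))
}

# Empirical survival function (no censoring): P(T > t).
oracle_ecdf_surv <- function(times, t) mean(times > t)

# Horizon confusion table by per-sample enumeration.
oracle_horizon <- function(scores, times, events, t, cutoff) {
  tab <- c(tp = 0, fp = 0, tn = 0, fn = 0, excl = 0)
  for (i in seq_along(scores)) {
    pred_alive <- scores[i] < cutoff
    if (times[i] < t && events[i] == 0) { tab["excl"] <- tab["excl"] + 1; next }
    alive <- !(events[i] == 1 && times[i] <= t)
    key <- if (pred_alive && alive) "tp" else if (pred_alive) "fp"
           else if (alive) "fn" else "tn"
    tab[key] <- tab[key] + 1
  }
  tab
}
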