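# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: textbook formulas, exhaustive enumeration, direct
# tabulation.

# textbook Pearson correlation
pearson_bf <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# AUC by exhaustive comparison of every (death, survivor) pair
auc_pairs_bf <- function(values, events) {
  d <- values[events]
  s <- values[!events]
  tot <- 0
  for (vd in d) for (vs in s)
    tot <- tot + (vd > vs) + 0.5 * (vd == vs)
  tot / (length(d) * length(s))
}

# AUC as trapezoidal area under the empirical ROC curve
auc_trapezoid_bf <- function(values, events) {
  thr <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(values[events] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(values[!events] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# exhaustive Youden search over every midpoint threshold; returns the
# maximal J and all cutoffs achieving it (orientation: high predicts death
# when flip = FALSE)
youden_bf <- function(values, events, flip = FALSE) {
  u <- sort(unique(values))
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(ct) {
    if (flip) {
      sens <- mean(values[events] <= ct)
      spec <- mean(values[!events] > ct)
    } else {
      sens <- mean(values[events] > ct)
      spec <- mean(values[!events] <= ct)
    }
    sens + spec - 1
  }, numeric(1))
  list(jmax = max(j), argmax = cand[j >= max(j) - 1e-12], cand = cand, j = j)
}

# product-limit estimator computed by direct tabulation
km_bf <- function(times, events) {
  events <- events == 1
  ts <- sort(unique(times[events]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# two-group log-rank by direct observed-minus-expected tabulation
logrank_bf <- function(times, events, groups) {
  events <- events == 1
  g <- factor(groups)
  stopifnot(nlevels(g) == 2)
  ts <- sort(unique(times[events]))
  o_minus_e <- 0
  v <- 0
  for (t in ts) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & g == levels(g)[1])
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & g == levels(g)[1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}
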