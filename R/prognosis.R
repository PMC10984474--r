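#' AUC for prediction of death from a single expression variable
#'
#' The area under the ROC curve computed as the Mann-Whitney rank statistic:
#' the probability that a randomly chosen patient who died has a higher
#' value than a randomly chosen survivor, ties counted 1/2. Identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param values numeric expression vector, one per patient
#' @param events logical or 0/1 death indicator
#' @return AUC in \[0, 1\]
#' @export
roc_auc_death <- function(values, events) {
  events <- check_events(values, events)
  n1 <- sum(events)
  n0 <- sum(!events)
  if (n1 == 0L || n0 == 0L)
    stop("degenerate input: need at least one death and one survivor")
  r <- rank(values)
  (sum(r[events]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_events <- function(values, events) {
  if (!is.numeric(values) || anyNA(values))
    stop("values must be numeric without missing entries")
  if (is.numeric(events)) {
    if (!all(events %in% c(0, 1))) stop("event must be 0/1")
    events <- events == 1
  }
  if (!is.logical(events) || anyNA(events) || length(events) != length(values))
    stop("events must be a logical/0-1 vector matching values")
  events
}

#' Best optimized expression cutoff for death prediction
#'
#' Searches the midpoints between consecutive sorted unique values for the
#' threshold maximizing the Youden index J = sensitivity + specificity - 1
#' on the death indicator. Orientation is automatic: when AUC >= 0.5 high
#' values predict death (patients above the cutoff form the "high" risk
#' group); when AUC < 0.5 the predictor is protective and sensitivity /
#' specificity are computed with the direction reversed, so a protective
#' gene still receives a meaningful dichotomization. Ties in J break toward
#' the cutoff giving more balanced group sizes, then toward the smaller
#' cutoff. A minimum group-size floor (fraction of the cohort per side)
#' guards against degenerate 1-vs-(n-1) splits.
#'
#' @inheritParams roc_auc_death
#' @param min_group_frac minimum fraction of patients required on each side
#'   of a candidate cutoff (default 0.1; at least 1 patient regardless)
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden`,
#'   `direction` (`">"` when high values predict death) and `n_high`,
#'   `n_low` group sizes.
#' @export
best_cutoff <- function(values, events, min_group_frac = 0.1) {
  events <- check_events(values, events)
  if (sum(events) == 0L || sum(!events) == 0L)
    stop("degenerate input: need at least one death and one survivor")
  u <- sort(unique(values))
  if (length(u) < 2L)
    stop("degenerate input: all expression values identical")
  cand <- (u[-1L] + u[-length(u)]) / 2
  n <- length(values)
  floor_n <- max(1L, ceiling(min_group_frac * n))
  n_high <- vapply(cand, function(ct) sum(values > ct), integer(1))
  ok <- n_high >= floor_n & (n - n_high) >= floor_n
  if (!any(ok)) ok <- rep(TRUE, length(cand)) # floor unsatisfiable: use all
  cand <- cand[ok]
  n_high <- n_high[ok]

  flip <- roc_auc_death(values, events) < 0.5
  sens <- vapply(cand, function(ct) {
    if (flip) mean(values[events] <= ct) else mean(values[events] > ct)
  }, numeric(1))
  spec <- vapply(cand, function(ct) {
    if (flip) mean(values[!events] > ct) else mean(values[!events] <= ct)
  }, numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  imbalance <- abs(n_high[best] - (n - n_high[best]))
  best <- best[order(imbalance, cand[best])]
  i <- best[1L]
  list(cutoff = cand[i], sensitivity = sens[i], specificity = spec[i],
       youden = j[i], direction = if (flip) "<" else ">",
       n_high = n_high[i], n_low = n - n_high[i])
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group (censored subjects leave the risk set
#' after their time), via [survival::survfit()].
#'
#' @param times follow-up times >= 0 (months)
#' @param events death indicator (1/TRUE = death, 0/FALSE = censored)
#' @param groups optional group labels; one curve per group
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` (step-function coordinates)
#' @export
km_estimate <- function(times, events, groups = NULL) {
  if (any(times < 0)) stop("times must be >= 0")
  events <- check_events(times, events)
  if (is.null(groups)) groups <- rep("all", length(times))
  if (any(table(factor(groups)) == 0L) || length(groups) != length(times))
    stop("groups must match times and have no empty level")
  df <- data.frame(times = times, events = as.integer(events),
                   groups = as.character(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(df$groups)[1L], length(s$time))
         else sub("^groups=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, n_censor = s$n.censor, surv = s$surv,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank statistic, chi-square with one
#' degree of freedom, via [survival::survdiff()].
#'
#' @inheritParams km_estimate
#' @param groups two-level group labels, both levels non-empty
#' @return list with `chi2` and `p`
#' @export
logrank_test <- function(times, events, groups) {
  events <- check_events(times, events)
  g <- factor(groups)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("log-rank needs exactly two non-empty groups")
  if (sum(events) == 0L)
    stop("log-rank needs at least one event")
  df <- data.frame(times = times, events = as.integer(events), g = g)
  sd <- survival::survdiff(survival::Surv(times, events) ~ g, data = df)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood estimates via [survival::coxph()] with the Efron
#' approximation for ties. Supports univariate and multivariate fits
#' (clinical covariates plus a gene or gene-group term). Fewer than 10
#' events triggers a warning; constant covariates are an error.
#'
#' @param data data.frame containing columns `time`, `event` and the
#'   covariates
#' @param variables character vector of covariate column names
#' @return data.frame with one row per coefficient: `term`, `beta`, `hr`,
#'   `ci_low`, `ci_high`, `p`
#' @export
cox_fit <- function(data, variables) {
  stopifnot(is.data.frame(data), all(c("time", "event") %in% names(data)),
            all(variables %in% names(data)))
  if (sum(data$event) < 10)
    warning("fewer than 10 events; Cox estimates may be unstable")
  for (v in variables) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2L)
      stop("constant covariate: ", v)
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(variables, collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox fit did not converge")
  s <- summary(fit)
  co <- s$coefficients
  ci <- s$conf.int
  out <- data.frame(term = rownames(co),
                    beta = co[, "coef"],
                    hr = co[, "exp(coef)"],
                    ci_low = ci[, "lower .95"],
                    ci_high = ci[, "upper .95"],
                    p = co[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Prognostic direction call from a dichotomized log-rank result
#'
#' `negative` when high expression carries significantly worse survival
#' (log-rank p < alpha and hazard ratio of the high group above 1),
#' `positive` when high expression is significantly protective, `ns`
#' otherwise.
#'
#' @param logrank_p log-rank p-value(s)
#' @param hr_high_vs_low hazard ratio(s) of the high-expression group
#' @param alpha significance level (default 0.05)
#' @return character vector in \{negative, positive, ns\}
#' @export
classify_direction <- function(logrank_p, hr_high_vs_low, alpha = 0.05) {
  ifelse(is.na(logrank_p) | is.na(hr_high_vs_low) | logrank_p >= alpha, "ns",
         ifelse(hr_high_vs_low > 1, "negative", "positive"))
}

#' Full per-gene prognostic evaluation
#'
#' The per-gene pipeline applied to one expression variable in a survival
#' cohort: AUC for death prediction, best optimized cutoff, dichotomization,
#' log-rank test, univariate Cox hazard ratio of the high group, and the
#' direction call. `cutoff_mode = "minp-logrank"` instead picks the cutoff
#' minimizing the log-rank p-value over the same candidate thresholds.
#'
#' Because the cutoff is optimized on the same data that is then tested, the
#' realized type-I error of the direction call exceeds the nominal alpha;
#' [measure_type1_level()] quantifies it.
#'
#' @param values expression vector
#' @param times,events survival outcome
#' @param alpha significance level for the direction call
#' @param min_group_frac see [best_cutoff()]
#' @param cutoff_mode `"youden"` (default) or `"minp-logrank"`
#' @param id gene/probe identifier recorded in the result
#' @return one-row data.frame (a `PrognosticResult`): `id`, `auc`, `cutoff`,
#'   `n_high`, `n_low`, `logrank_p`, `hr_high_vs_low`, `direction`
#' @export
evaluate_gene <- function(values, times, events, alpha = 0.05,
                          min_group_frac = 0.1,
                          cutoff_mode = c("youden", "minp-logrank"),
                          id = "gene") {
  cutoff_mode <- match.arg(cutoff_mode)
  events <- check_events(values, events)
  auc <- roc_auc_death(values, events)
  if (cutoff_mode == "youden") {
    bc <- best_cutoff(values, events, min_group_frac = min_group_frac)
    cutoff <- bc$cutoff
  } else {
    cutoff <- minp_logrank_cutoff(values, times, events, min_group_frac)
  }
  high <- values > cutoff
  lr <- logrank_test(times, events, ifelse(high, "high", "low"))
  cx <- cox_fit(data.frame(time = times, event = as.integer(events),
                           high = as.integer(high)), "high")
  hr <- cx$hr[1L]
  data.frame(id = id, auc = auc, cutoff = cutoff,
             n_high = sum(high), n_low = sum(!high),
             logrank_p = lr$p, hr_high_vs_low = hr,
             direction = classify_direction(lr$p, hr, alpha),
             stringsAsFactors = FALSE)
}

minp_logrank_cutoff <- function(values, times, events, min_group_frac) {
  u <- sort(unique(values))
  if (length(u) < 2L) stop("degenerate input: all expression values identical")
  cand <- (u[-1L] + u[-length(u)]) / 2
  n <- length(values)
  floor_n <- max(1L, ceiling(min_group_frac * n))
  n_high <- vapply(cand, function(ct) sum(values > ct), integer(1))
  ok <- n_high >= floor_n & (n - n_high) >= floor_n
  if (!any(ok)) ok <- rep(TRUE, length(cand))
  cand <- cand[ok]
  p <- vapply(cand, function(ct) {
    g <- values > ct
    if (all(g) || !any(g)) return(1)
    logrank_test(times, events, ifelse(g, "high", "low"))$p
  }, numeric(1))
  cand[which.min(p)]
}

#' Order prognostic results by AUC
#'
#' Descending AUC; ties break by gene id.
#'
#' @param results data.frame of `PrognosticResult` rows (columns `id`, `auc`)
#' @return the same data.frame, reordered
#' @export
rank_by_auc <- function(results) {
  stopifnot(all(c("id", "auc") %in% names(results)))
  out <- results[order(-results$auc, results$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-gene combined stratification
#'
#' Splits the cohort by gene A's best cutoff (computed on the full cohort),
#' then within each A-stratum dichotomizes by gene B's full-cohort cutoff
#' and runs a log-rank test of B. This probes whether B stratifies prognosis
#' conditionally on A (e.g. a cytotoxic-T-cell marker stratifying only when
#' a fibroblast collagen gene is low). A stratum where B yields a single
#' group, has fewer than 2 patients per B-group, or no events is reported as
#' not evaluable rather than an error.
#'
#' @param values_a,values_b expression vectors of genes A and B
#' @param times,events survival outcome
#' @param min_group_frac see [best_cutoff()]
#' @return list with `cutoff_a`, `cutoff_b` and `strata`: per A-stratum
#'   (`A_low`, `A_high`) a list with `n`, `evaluable`, `chi2`, `p`, `km`
#'   (Kaplan-Meier coordinates of the B groups, `NULL` when not evaluable)
#' @export
combined_stratification <- function(values_a, values_b, times, events,
                                    min_group_frac = 0.1) {
  events <- check_events(values_a, events)
  cut_a <- best_cutoff(values_a, events, min_group_frac)$cutoff
  cut_b <- best_cutoff(values_b, events, min_group_frac)$cutoff
  strata <- list()
  for (lab in c("A_low", "A_high")) {
    sel <- if (lab == "A_low") values_a <= cut_a else values_a > cut_a
    res <- list(n = sum(sel), evaluable = FALSE,
                chi2 = NA_real_, p = NA_real_, km = NULL)
    if (sum(sel) >= 4L) {
      g <- ifelse(values_b[sel] > cut_b, "B_high", "B_low")
      tab <- table(factor(g, levels = c("B_low", "B_high")))
      if (all(tab >= 2L) && sum(events[sel]) >= 1L) {
        lr <- logrank_test(times[sel], events[sel], g)
        res$evaluable <- TRUE
        res$chi2 <- lr$chi2
        res$p <- lr$p
        res$km <- km_estimate(times[sel], events[sel], g)
      }
    }
    strata[[lab]] <- res
  }
  list(cutoff_a = cut_a, cutoff_b = cut_b, strata = strata)
}

#' Measure the realized type-I level of the per-gene pipeline
#'
#' Runs [evaluate_gene()] on pure-noise genes in simulated null cohorts and
#' reports the fraction called significant (direction not `ns`) at the given
#' alpha. Because the cutoff is optimized before testing, this measured
#' level is expected to exceed alpha; it is reported, never asserted equal
#' to alpha.
#'
#' @param n_patients cohort size per simulation
#' @param n_sim number of simulated null genes
#' @param alpha nominal level
#' @param baseline_hazard,censor_rate cohort generation parameters, see
#'   [generate_survival_cohort()]
#' @param seed RNG seed
#' @return list with `measured_level`, `nominal_alpha`, `n_sim`
#' @export
measure_type1_level <- function(n_patients = 232, n_sim = 100, alpha = 0.05,
                                baseline_hazard = 0.02, censor_rate = 0.4,
                                seed = 1) {
  set.seed(seed)
  hits <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    haz <- rep(baseline_hazard, n_patients)
    t_event <- stats::rexp(n_patients, rate = haz)
    t_cens <- if (censor_rate <= 0) rep(Inf, n_patients)
      else stats::rexp(n_patients,
                       rate = baseline_hazard * censor_rate / (1 - censor_rate))
    times <- pmin(t_event, t_cens)
    ev <- t_event <= t_cens
    x <- stats::rnorm(n_patients)
    res <- evaluate_gene(x, times, ev, alpha = alpha)
    hits[i] <- res$direction != "ns"
  }
  list(measured_level = mean(hits), nominal_alpha = alpha, n_sim = n_sim)
}
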