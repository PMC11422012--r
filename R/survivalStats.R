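# Survival machinery: Kaplan-Meier, log-rank, maximally selected cutpoint,
# Cox proportional hazards. Estimators are delegated to the survival
# package; the cutpoint scan and its corrected p-value are authored here.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood standard errors and median
#' survival (first time S(t) <= 0.5; `NA` = not reached).
#'
#' @param times event/censoring times (> 0).
#' @param events 0/1 event indicators.
#' @param weights optional case weights (IPTW).
#' @return list of class `kmCurve`: `time`, `surv`, `nRisk`, `stdErr`,
#'   `median`, `n`.
#' @export
kmEstimate <- function(times, events, weights = NULL) {
  df <- data.frame(times = times, events = as.integer(events))
  fit <- if (is.null(weights))
    survival::survfit(survival::Surv(times, events) ~ 1, data = df)
  else
    survival::survfit(survival::Surv(times, events) ~ 1, data = df,
                      weights = weights)
  # median = first time S(t) <= 0.5 ("not reached" -> NA)
  med <- if (any(fit$surv <= 0.5 + 1e-12))
    fit$time[which(fit$surv <= 0.5 + 1e-12)[1L]] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
                 stdErr = fit$std.err * fit$surv,  # Greenwood, surv scale
                 median = med, n = length(times)),
            class = "kmCurve")
}

#' Median survival from a KM curve
#'
#' @param km a `kmCurve`.
#' @return numeric median, or `NA` when not reached.
#' @export
medianSurvival <- function(km) km$median

#' Log-rank test
#'
#' Standard O-E statistic with hypergeometric variance across >= 2 groups.
#'
#' @param times,events survival data.
#' @param group group labels (>= 2 levels).
#' @return list with `chi2`, `df`, `p`, and per-group `observed`/`expected`.
#' @export
logrankTest <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("log-rank needs at least 2 groups")
  if (sum(events) < 1L) stop("log-rank needs at least one event")
  df <- data.frame(times = times, events = as.integer(events),
                   group = group)
  sd <- survival::survdiff(survival::Surv(times, events) ~ group, data = df)
  dfree <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = dfree,
       p = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

# Lausen-Schumacher approximate p-value for a maximally selected log-rank
# statistic: P(sup |B(t)/sqrt(t(1-t))| > b) over t in [eps1, eps2].
maxstatP <- function(b, eps1, eps2) {
  if (!is.finite(b) || b <= 0) return(1)
  phi <- stats::dnorm(b)
  p <- 4 * phi / b +
    phi * (b - 1 / b) * log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2)))
  min(max(p, 2 * stats::pnorm(-b)), 1)
}

#' Maximally selected survival cutpoint
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct sorted
#' scores whose induced groups both hold at least `minGroupProportion` of
#' patients) and selects the minimum log-rank p; ties go to the larger
#' minority group, then the lower cutpoint. Patients with score strictly
#' above the cutpoint are labelled `positive` (predicted sensitive, by the
#' projection orientation). Alongside the at-cutpoint log-rank p (which is
#' optimistic, being a minimum over the scan; the number of candidates is
#' reported so users can assess that optimism), the Lausen-Schumacher
#' corrected p-value for the maximally selected statistic is returned as
#' `adjustedP`.
#'
#' @param scores named numeric score per patient.
#' @param times,events survival data aligned with `scores`.
#' @param minGroupProportion minimum per-group fraction (default 0.10).
#' @return list of class `stratification`: `cutpoint`, `labels` (named
#'   logical, TRUE = positive), `chi2`, `p`, `adjustedP`, `nCandidates`,
#'   `hr`/`ciLow`/`ciHigh`/`hrP` (univariate Cox on the label), and
#'   per-group `km` curves.
#' @export
bestCutpoint <- function(scores, times, events, minGroupProportion = 0.10) {
  n <- length(scores)
  if (n < 10L) stop("need at least 10 patients")
  su <- sort(unique(scores))
  if (length(su) < 2L) stop("need at least 2 distinct scores")
  cuts <- (su[-1] + su[-length(su)]) / 2
  minSize <- minGroupProportion * n
  ok <- vapply(cuts, function(ct) {
    hi <- sum(scores > ct)
    min(hi, n - hi) >= minSize - 1e-9
  }, logical(1))
  cuts <- cuts[ok]
  if (length(cuts) == 0L)
    stop("no cutpoint satisfies the minimum group proportion")
  stat <- t(vapply(cuts, function(ct) {
    lr <- logrankTest(times, events, scores > ct)
    c(p = lr$p, chi2 = lr$chi2, minority = min(sum(scores > ct),
                                               sum(scores <= ct)))
  }, numeric(3)))
  o <- order(stat[, "p"], -stat[, "minority"], cuts)
  pick <- o[1L]
  cut <- cuts[pick]
  labels <- stats::setNames(scores > cut, names(scores))
  lr <- logrankTest(times, events, labels)
  b <- sqrt(max(stat[, "chi2"]))
  adjP <- maxstatP(b, minGroupProportion, 1 - minGroupProportion)
  # univariate Cox on the label; extreme separations yield NA with a note
  cox <- tryCatch(
    coxFit(data.frame(positive = as.integer(labels)), times, events),
    error = function(e) {
      warning(sprintf("cutpoint hazard ratio unavailable: %s",
                      conditionMessage(e)), call. = FALSE)
      data.frame(hr = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
                 p = NA_real_)
    })
  kmPos <- kmEstimate(times[labels], events[labels])
  kmNeg <- kmEstimate(times[!labels], events[!labels])
  structure(list(cutpoint = cut, labels = labels, chi2 = lr$chi2, p = lr$p,
                 adjustedP = adjP, nCandidates = length(cuts),
                 hr = cox$hr[1], ciLow = cox$ciLow[1],
                 ciHigh = cox$ciHigh[1], hrP = cox$p[1],
                 km = list(positive = kmPos, negative = kmNeg)),
            class = "stratification")
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood Newton-Raphson with Efron tie handling (survival
#' package engine); Wald 95% CIs. Monotone-likelihood separation is
#' detected and raised as a diagnostic error rather than returned as a
#' silently diverged estimate.
#'
#' @param covariates data.frame (or matrix) of patient covariates; factors
#'   are expanded by the usual model matrix rules.
#' @param times,events survival data.
#' @param tieMethod `"efron"` (default) or `"breslow"`.
#' @return data.frame with one row per coefficient: `term`, `beta`, `se`,
#'   `hr`, `ciLow`, `ciHigh`, `p`; attributes `loglik` and `converged`.
#' @export
coxFit <- function(covariates, times, events,
                   tieMethod = c("efron", "breslow")) {
  tieMethod <- match.arg(tieMethod)
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop(sprintf("covariate '%s' is constant", nm))
  }
  if (sum(events) < ncol(covariates))
    stop("fewer events than covariates")
  df <- cbind(data.frame(.time = times, .event = as.integer(events)),
              covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = df, ties = tieMethod,
    control = survival::coxph.control(eps = 1e-11, iter.max = 50))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(abs(beta) > 15) || any(se > 10))
    stop("monotone likelihood (separation) detected; Cox estimate unstable")
  z <- beta / se
  out <- data.frame(term = names(beta), beta = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    ciLow = exp(unname(beta - 1.96 * se)),
                    ciHigh = exp(unname(beta + 1.96 * se)),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    row.names = NULL)
  attr(out, "loglik") <- fit$loglik
  attr(out, "converged") <- fit$info %||% TRUE
  out
}
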