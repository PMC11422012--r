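# Dose-response viability scoring for PDC/PDO panels: 4-parameter logistic
# fit in log10(dose) and range-normalized area under the fitted curve, with
# an optional growth-rate (replication-rate) correction.

#' Construct/validate a dose-response panel
#'
#' @param doses concentrations in mol/L (one per observation row).
#' @param viability fraction-of-control viabilities (>= 0).
#' @param modelId,drug identifiers carried through to scores.
#' @param replicationRate optional divisions per assay window, used by the
#'   growth-rate correction in \code{\link{viabilityAUC}}.
#' @return A list of class `doseResponsePanel`.
#' @export
doseResponsePanel <- function(doses, viability, modelId = NA_character_,
                              drug = NA_character_, replicationRate = NULL) {
  if (length(doses) != length(viability))
    stop("doses and viability lengths differ")
  if (any(doses <= 0)) stop("doses must be positive (mol/L)")
  if (any(!is.finite(viability)) || any(viability < 0))
    stop("viability must be finite and >= 0")
  if (length(unique(doses)) < 5L)
    stop("need at least 5 distinct doses")
  structure(list(doses = doses, viability = viability, modelId = modelId,
                 drug = drug, replicationRate = replicationRate),
            class = "doseResponsePanel")
}

#' Per-model drug response score
#'
#' Lower values mean greater sensitivity for both metrics (viability AUC and
#' POR).
#'
#' @param modelId,drug identifiers.
#' @param metric `"viability_auc"` or `"por"`.
#' @param value non-negative score.
#' @return A list of class `responseScore`.
#' @export
responseScore <- function(modelId, drug, metric = c("viability_auc", "por"),
                          value) {
  metric <- match.arg(metric)
  if (!is.finite(value) || value < 0)
    stop(sprintf("%s must be finite and >= 0", metric))
  structure(list(modelId = modelId, drug = drug, metric = metric,
                 value = value), class = "responseScore")
}

.fourPL <- function(x, upper, lower, le, hill) {
  lower + (upper - lower) / (1 + 10^(hill * (x - le)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL in log10(dose),
#' `v(x) = lower + (upper - lower) / (1 + 10^(hill * (x - log10(ec50))))`
#' with `hill > 0` (viability decreasing with dose). Multi-start
#' Levenberg-Marquardt over a grid of EC50 and Hill initializations; the
#' `converged` flag reports honest convergence of the best start.
#'
#' @param panel a `doseResponsePanel` (or anything accepted by
#'   \code{\link{doseResponsePanel}} via `doses`/`viability` arguments).
#' @param doses,viability alternative to `panel`.
#' @return A list of class `sigmoidFit` with elements `upper`, `lower`,
#'   `ec50`, `hill`, `rss`, `converged` and `predict(log10dose)`.
#' @export
fitDoseResponse <- function(panel = NULL, doses = NULL, viability = NULL) {
  if (is.null(panel)) panel <- doseResponsePanel(doses, viability)
  x <- log10(panel$doses)
  v <- panel$viability
  if (stats::sd(v) < 1e-9) {
    # inactive drug: flat curve, upper == lower
    fit <- list(upper = mean(v), lower = mean(v),
                ec50 = 10^mean(range(x)), hill = 1,
                rss = sum((v - mean(v))^2), converged = TRUE)
    fit$predict <- function(lx) rep(fit$upper, length(lx))
    class(fit) <- "sigmoidFit"
    return(fit)
  }
  top <- stats::quantile(v, 0.95, names = FALSE)
  bot <- max(0, stats::quantile(v, 0.05, names = FALSE))
  starts <- expand.grid(
    le = seq(min(x) - 1, max(x) + 1, length.out = 5),
    hill = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        v ~ lower + (upper - lower) / (1 + 10^(hill * (x - le))),
        start = list(upper = top, lower = bot, le = starts$le[i],
                     hill = starts$hill[i]),
        lower = c(upper = 0, lower = 0, le = min(x) - 4, hill = 0.05),
        upper = c(upper = 2 * max(v) + 0.1, lower = max(v), le = max(x) + 4,
                  hill = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    conv <- f$convInfo$isConv %||% TRUE
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(coef = stats::coef(f), rss = rss, converged = conv)
  }
  if (is.null(best))
    stop("dose-response fit failed from every start")
  cf <- as.list(best$coef)
  if (cf$upper < cf$lower) {  # enforce upper >= lower labelling
    tmp <- cf$upper; cf$upper <- cf$lower; cf$lower <- tmp
  }
  fit <- list(upper = cf$upper, lower = cf$lower, ec50 = 10^cf$le,
              hill = cf$hill, rss = best$rss, converged = best$converged)
  fit$predict <- function(lx) .fourPL(lx, cf$upper, cf$lower, cf$le, cf$hill)
  class(fit) <- "sigmoidFit"
  fit
}

#' Range-normalized viability AUC from a fitted curve
#'
#' Trapezoidal integral of the fitted viability over log10(dose) on a
#' 201-point grid, divided by the log-range width, so a fully resistant
#' model (viability 1 everywhere) scores 1 and a fully sensitive one 0.
#' When `replicationRate` is supplied, viability is first mapped to the
#' growth-rate-normalized response `2^(log2(v)/replicationRate) - 1`,
#' rescaled from [-1, 1] to [0, 1], before integration.
#'
#' @param fit a `sigmoidFit`.
#' @param doseRange integration range in mol/L (default `c(1e-9, 1e-3)`).
#' @param replicationRate optional divisions per assay window.
#' @param modelId,drug identifiers for the returned score.
#' @param nGrid grid size (default 201).
#' @return A `responseScore` with metric `"viability_auc"`.
#' @export
viabilityAUC <- function(fit, doseRange = c(1e-9, 1e-3),
                         replicationRate = NULL, modelId = NA_character_,
                         drug = NA_character_, nGrid = 201L) {
  if (!inherits(fit, "sigmoidFit")) stop("fit must be a sigmoidFit")
  if (!isTRUE(fit$converged))
    stop("fit did not converge; use rawTrapezoidAUC on the raw panel instead")
  x <- seq(log10(doseRange[1]), log10(doseRange[2]), length.out = nGrid)
  v <- pmax(fit$predict(x), 0)
  if (!is.null(replicationRate)) {
    if (replicationRate <= 0) stop("replicationRate must be positive")
    gr <- 2^(log2(pmax(v, 1e-12)) / replicationRate) - 1
    v <- (pmin(pmax(gr, -1), 1) + 1) / 2
  }
  auc <- trapz(x, v) / (max(x) - min(x))
  responseScore(modelId, drug, "viability_auc", auc)
}

#' Raw trapezoid AUC fallback
#'
#' Range-normalized trapezoid on per-dose mean viabilities, for panels whose
#' sigmoid fit did not converge.
#'
#' @param doses concentrations in mol/L.
#' @param viability viability per observation.
#' @return Normalized AUC in log10(dose).
#' @export
rawTrapezoidAUC <- function(doses, viability) {
  mu <- tapply(viability, log10(doses), mean)
  x <- as.numeric(names(mu))
  o <- order(x)
  trapz(x[o], as.numeric(mu)[o]) / (max(x) - min(x))
}
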