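# PDX growth-curve response: 3-parameter logistic fit of tumor volume over
# time and the AUC-ratio resistance score (POR).

#' Caliper tumor volume (ellipsoid approximation)
#'
#' `v = length * width^2 / 2`, in mm3 for caliper measurements in mm.
#'
#' @param length,width caliper measurements (mm), `length >= width`.
#' @return volume in mm3.
#' @export
tumorVolume <- function(length, width) length * width^2 / 2

#' Construct/validate a growth-curve set for one PDX arm
#'
#' Observations are sorted by day within mouse; measurements after a mouse
#' first exceeds 2000 mm3 (ethical sacrifice threshold) are flagged censored
#' and excluded from fitting.
#'
#' @param df data.frame with columns `day`, `volume` and optionally `mouse`
#'   (single mouse assumed when absent).
#' @param pdxId PDX identifier.
#' @param arm `"control"` or `"treated"`.
#' @return A list of class `growthCurveSet` with a `censored` flag column.
#' @export
growthCurveSet <- function(df, pdxId = NA_character_,
                           arm = c("control", "treated")) {
  arm <- match.arg(arm)
  if (!all(c("day", "volume") %in% names(df)))
    stop("growth data needs 'day' and 'volume' columns")
  if (is.null(df$mouse)) df$mouse <- "m1"
  if (any(!is.finite(df$day)) || any(!is.finite(df$volume)))
    stop("day and volume must be finite")
  if (any(df$volume < 0)) stop("volumes must be >= 0")
  df <- df[order(df$mouse, df$day), , drop = FALSE]
  df$censored <- unlist(lapply(split(df$volume, df$mouse), function(v) {
    over <- cumsum(v > 2000) > 0
    c(FALSE, utils::head(over, -1))  # censored after first exceedance
  }), use.names = FALSE)
  structure(list(data = df, pdxId = pdxId, arm = arm),
            class = "growthCurveSet")
}

#' Fit a logistic growth curve to all mice of one arm
#'
#' 3-parameter logistic `V(t) = Vmax / (1 + exp(-k * (t - t0)))` fit jointly
#' to all replicate mice by Levenberg-Marquardt least squares. Flat series
#' return a constant fit; monotone-decreasing series are fit with `Vmax`
#' pinned at the initial mean volume and flagged.
#'
#' @param curves a `growthCurveSet` (censored points excluded).
#' @return A list of class `growthFit` with `Vmax`, `k`, `t0`, `rss`,
#'   `converged`, `flags` and `predict(day)`.
#' @export
fitGrowthCurve <- function(curves) {
  if (!inherits(curves, "growthCurveSet"))
    stop("curves must be a growthCurveSet")
  d <- curves$data[!curves$data$censored, , drop = FALSE]
  if (length(unique(d$day)) < 3L) stop("need at least 3 observation days")
  t <- d$day
  vscale <- max(d$volume)  # fit on normalized volumes: scale equivariance
  if (vscale <= 0) vscale <- 1
  v <- d$volume / vscale
  flags <- character()
  if (stats::sd(v) < 1e-9) {
    fit <- list(Vmax = mean(v) * vscale, k = 0, t0 = NA_real_, rss = 0,
                converged = TRUE, flags = "flat")
    fit$predict <- function(day) rep(fit$Vmax, length(day))
    class(fit) <- "growthFit"
    return(fit)
  }
  first <- mean(v[t == min(t)]); last <- mean(v[t == max(t)])
  decreasing <- last < first
  if (decreasing) {
    flags <- c(flags, "decreasing")
    Vmax0 <- max(first, 1e-6)
    f <- tryCatch(minpack.lm::nlsLM(
      v ~ Vmax0 / (1 + exp(-k * (t - t0))),
      start = list(k = -0.05, t0 = stats::median(t)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    cf <- if (is.null(f)) c(k = 0, t0 = stats::median(t)) else stats::coef(f)
    fit <- list(Vmax = Vmax0 * vscale, k = unname(cf["k"]),
                t0 = unname(cf["t0"]),
                rss = vscale^2 * (if (is.null(f)) sum((v - Vmax0)^2)
                                  else sum(stats::residuals(f)^2)),
                converged = !is.null(f), flags = flags)
  } else {
    f <- NULL
    for (k0 in c(0.05, 0.1, 0.2)) {
      fi <- tryCatch(minpack.lm::nlsLM(
        v ~ Vmax / (1 + exp(-k * (t - t0))),
        start = list(Vmax = 1.1 * max(v), k = k0, t0 = stats::median(t)),
        lower = c(Vmax = 1e-6, k = 1e-4, t0 = min(t) - 200),
        upper = c(Vmax = 50 * max(v), k = 5, t0 = max(t) + 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fi) &&
          (is.null(f) || sum(stats::residuals(fi)^2) <
                         sum(stats::residuals(f)^2)))
        f <- fi
    }
    if (is.null(f)) stop("growth-curve fit failed")
    cf <- stats::coef(f)
    fit <- list(Vmax = unname(cf["Vmax"]) * vscale, k = unname(cf["k"]),
                t0 = unname(cf["t0"]),
                rss = vscale^2 * sum(stats::residuals(f)^2),
                converged = isTRUE(f$convInfo$isConv), flags = flags)
  }
  fit$predict <- function(day) fit$Vmax / (1 + exp(-fit$k * (day - fit$t0)))
  class(fit) <- "growthFit"
  fit
}

#' Percentage of resistance (POR) for one PDX
#'
#' `POR = AUC_treated(0..tMax) / AUC_control(0..tMax)`; both arms are
#' integrated over the identical day interval. `"fitted"` (default)
#' evaluates the per-arm logistic fits on a shared 201-point grid;
#' `"raw"` trapezoids the per-day mean volumes.
#'
#' @param treated,control `growthCurveSet`s from the same PDX.
#' @param tMax upper integration limit in days; defaults to the last day
#'   common to both arms.
#' @param method `"fitted"` or `"raw"`.
#' @return A `responseScore` with metric `"por"` (1 = no effect, 0 = full
#'   regression).
#' @export
por <- function(treated, control, tMax = NULL,
                method = c("fitted", "raw")) {
  method <- match.arg(method)
  if (!inherits(treated, "growthCurveSet") ||
      !inherits(control, "growthCurveSet"))
    stop("both arms must be growthCurveSets")
  if (!is.na(treated$pdxId) && !is.na(control$pdxId) &&
      !identical(treated$pdxId, control$pdxId))
    stop(sprintf("mismatched pdx ids: %s vs %s", treated$pdxId,
                 control$pdxId))
  lastCommon <- min(max(treated$data$day), max(control$data$day))
  if (is.null(tMax)) tMax <- lastCommon
  if (tMax > lastCommon + 1e-9)
    stop("tMax exceeds the last day common to both arms")
  t0 <- max(min(treated$data$day), min(control$data$day))
  if (method == "fitted") {
    grid <- seq(t0, tMax, length.out = 201L)
    aucT <- trapz(grid, pmax(fitGrowthCurve(treated)$predict(grid), 0))
    aucC <- trapz(grid, pmax(fitGrowthCurve(control)$predict(grid), 0))
  } else {
    armAuc <- function(g) {
      d <- g$data[!g$data$censored & g$data$day >= t0 & g$data$day <= tMax +
                    1e-9, ]
      mu <- tapply(d$volume, d$day, mean)
      trapz(as.numeric(names(mu)), as.numeric(mu))
    }
    aucT <- armAuc(treated); aucC <- armAuc(control)
  }
  if (aucC <= 0) stop("control AUC is zero; POR undefined")
  responseScore(control$pdxId, treated$drug %||% NA_character_, "por",
                aucT / aucC)
}
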