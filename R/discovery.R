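# Discovery-cohort selection: the 6 + 6 PDCs in the AUC percentile bands
# [P10, P25] (sensitive) and [P75, P90] (resistant).

#' Select discovery samples by AUC percentile bands
#'
#' Samples whose AUC lies within the [P10, P25] band form the sensitive pool
#' and [P75, P90] the resistant pool (type-7 linear-interpolation
#' quantiles). When a band holds more than `nPerGroup` samples, the
#' `nPerGroup` closest to the band midpoint are kept; fewer is an error.
#' AUC ties are broken by identifier order (with a message).
#'
#' @param aucs named numeric vector of viability AUCs (lower = more
#'   sensitive).
#' @param nPerGroup samples per band (default 6).
#' @return list with `sensitive` and `resistant` identifier vectors and the
#'   band limits.
#' @export
selectDiscoverySamples <- function(aucs, nPerGroup = 6L) {
  if (is.null(names(aucs)) || anyDuplicated(names(aucs)))
    stop("aucs must be uniquely named by sample")
  if (length(aucs) < 2L * nPerGroup)
    stop(sprintf("need at least %d samples", 2L * nPerGroup))
  assertFiniteNumeric(aucs, "aucs")
  if (stats::sd(aucs) < 1e-12)
    stop("degenerate AUC distribution (all values equal)")
  if (anyDuplicated(aucs))
    message("AUC ties present; broken by identifier order")
  q <- stats::quantile(aucs, c(0.10, 0.25, 0.75, 0.90), type = 7,
                       names = FALSE)
  ord <- order(aucs, names(aucs))
  sortedIds <- names(aucs)[ord]
  sortedAuc <- aucs[ord]
  pickBand <- function(lo, hi, label) {
    inBand <- sortedIds[sortedAuc >= lo & sortedAuc <= hi]
    if (length(inBand) < nPerGroup)
      stop(sprintf(
        "%s band [P%s] holds %d samples (< %d); enlarge the cohort",
        label, if (label == "sensitive") "10,P25" else "75,P90",
        length(inBand), nPerGroup))
    if (length(inBand) > nPerGroup) {
      mid <- (lo + hi) / 2
      inBand <- inBand[order(abs(aucs[inBand] - mid))][seq_len(nPerGroup)]
      inBand <- sortedIds[sortedIds %in% inBand]
    }
    inBand
  }
  sens <- pickBand(q[1], q[2], "sensitive")
  res <- pickBand(q[3], q[4], "resistant")
  list(sensitive = sens, resistant = res,
       bands = list(sensitive = q[1:2], resistant = q[3:4]))
}
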