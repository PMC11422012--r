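# Categorical response statistics: exact binomial ORR with Clopper-Pearson
# CI, Pearson chi-square, and combination (sensitive-drug-count) profiles.

#' Objective response rate with exact binomial inference
#'
#' ORR = (#CR + #PR) / n within the group; Clopper-Pearson 95% CI and
#' two-sided exact binomial p versus `p0`. `p0` defaults to the
#' pooled-cohort ORR computed over all `responses` (configurable).
#'
#' @param responses character vector of CR/PR/SD/PD over the whole cohort.
#' @param group optional logical/index subset defining the tested group
#'   (default: all).
#' @param p0 null response proportion in (0, 1).
#' @param conf confidence level (default 0.95).
#' @return list with `orr`, `ciLow`, `ciHigh`, `p`, `k`, `n`, `p0`.
#' @export
orrExact <- function(responses, group = NULL, p0 = NULL, conf = 0.95) {
  stopifnot(all(responses %in% c("CR", "PR", "SD", "PD")))
  if (is.null(p0)) p0 <- mean(responses %in% c("CR", "PR"))
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  sub <- if (is.null(group)) responses else responses[group]
  if (length(sub) == 0L) stop("group is empty")
  k <- sum(sub %in% c("CR", "PR"))
  n <- length(sub)
  bt <- stats::binom.test(k, n, p = p0, conf.level = conf)
  list(orr = k / n, ciLow = bt$conf.int[1], ciHigh = bt$conf.int[2],
       p = bt$p.value, k = k, n = n, p0 = p0)
}

#' Pearson chi-square test on an r x c count table
#'
#' Without continuity correction; a warning is issued when any expected
#' count is below 5.
#'
#' @param table r x c matrix of counts.
#' @return list with `chi2`, `df`, `p` and the `expected` table.
#' @export
chiSquareTest <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  if (any(ct$expected < 5))
    warning("expected count below 5; chi-square approximation is weak")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Combine per-drug stratification labels into a sensitivity-count profile
#'
#' @param strats named list of three `stratification` results (or named
#'   logical label vectors), one per drug, over the same patient set.
#' @return data.frame with per-drug logical columns, `sensitiveCount`
#'   (0-3) and `countFactor` (factor with 0 as reference level for
#'   downstream Cox models).
#' @export
combineDrugLabels <- function(strats) {
  labs <- lapply(strats, function(s)
    if (inherits(s, "stratification")) s$labels else s)
  ids <- names(labs[[1L]])
  if (is.null(ids)) stop("labels must be named by patient")
  for (l in labs)
    if (!setequal(names(l), ids) || length(l) != length(ids))
      stop("mismatched patient sets across stratifications")
  labs <- lapply(labs, function(l) l[ids])
  out <- data.frame(id = ids, row.names = NULL)
  for (d in names(labs)) out[[d]] <- as.logical(labs[[d]])
  out$sensitiveCount <- Reduce(`+`, lapply(labs, as.integer))
  out$countFactor <- droplevels(factor(out$sensitiveCount,
                                       levels = 0:length(labs)))
  out
}
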