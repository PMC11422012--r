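# TMM scaling factors and log2-CPM normalization of count matrices, the
# preprocessing applied before ICA and signature projection.

#' Trimmed-mean-of-M-values (TMM) scaling factors
#'
#' Computes per-sample TMM normalization factors (edgeR's method): M-values
#' (log2 ratios of library-normalized counts against a reference sample) are
#' doubly trimmed by `trimM`, A-values (log2 abundances) by `trimA`, and the
#' factor is 2^(precision-weighted mean of surviving M-values), recentered so
#' the factors have geometric mean 1. The reference sample is the one whose
#' upper quartile of scaled counts is closest to the mean upper quartile.
#'
#' @param counts a \linkS4class{ChemoExpr} in `raw_counts` state, or a
#'   non-negative integer matrix.
#' @param trimM two-sided trim fraction for M-values (default 0.30).
#' @param trimA two-sided trim fraction for A-values (default 0.05).
#' @return Named numeric vector of strictly positive factors with geometric
#'   mean 1.
#' @export
tmmFactors <- function(counts, trimM = 0.30, trimA = 0.05) {
  m <- .countMatrix(counts)
  if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
  zero <- colSums(m) == 0
  if (any(zero))
    stop(sprintf("all-zero sample(s): %s",
                 paste(colnames(m)[zero], collapse = ", ")))
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trimM,
                              sumTrim = trimA)
  stats::setNames(as.numeric(f), colnames(m))
}

#' TMM + log2-CPM normalization
#'
#' `value(g, s) = log2(count(g, s) / (libsize(s) * factor(s)) * 1e6 + prior)`.
#'
#' @param counts a \linkS4class{ChemoExpr} in `raw_counts` state, or count
#'   matrix.
#' @param factors per-sample scaling factors from \code{\link{tmmFactors}};
#'   computed from `counts` when `NULL`.
#' @param prior pseudocount added to the CPM before log2 (default 1, so a
#'   zero count maps to 0).
#' @return A \linkS4class{ChemoExpr} in `tmm_log2` state.
#' @export
normalizeLog2 <- function(counts, factors = NULL, prior = 1) {
  m <- .countMatrix(counts)
  if (is.null(factors)) factors <- tmmFactors(counts)
  if (is.null(names(factors)) ||
      !setequal(names(factors), colnames(m)) ||
      length(factors) != ncol(m))
    stop("factors do not match the sample set of the count matrix")
  factors <- factors[colnames(m)]
  lib <- colSums(m)
  out <- log2(sweep(m, 2L, lib * factors, "/") * 1e6 + prior)
  ChemoExpr(out, state = "tmm_log2")
}

.countMatrix <- function(counts) {
  if (is(counts, "ChemoExpr")) {
    if (!identical(normState(counts), "raw_counts"))
      stop("expected a raw_counts ChemoExpr")
    return(exprValues(counts))
  }
  m <- as.matrix(counts)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-8))
    stop("counts must be non-negative integers")
  m
}
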