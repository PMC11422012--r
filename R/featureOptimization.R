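# Feature-count optimization: shrink a response component to the smallest
# gene set whose projected score best correlates with response in an
# independent validation cohort, scanning |weight| thresholds in SD steps.

#' Optimize the signature feature count on a validation cohort
#'
#' Candidate gene sets contain the genes with `|weight| > m * SD(weights)`
#' for `m` descending from `mMax` to 0 in steps of `sdStep` (default 0.5,
#' refining the one-SD-interval scan; set `sdStep = 1` for the coarse
#' variant). Each candidate is projected onto the validation expression and
#' scored by |Spearman rho| against the validation AUCs. The returned set
#' is the smallest one whose correlation is statistically indistinguishable
#' from the scan maximum: a one-standard-error rule on the Fisher-z scale
#' (`atanh|rho| >= max - 1/sqrt(n - 3)`), which implements "the minimum
#' number of genes with the highest correlation coefficient" without letting
#' sub-noise-level rho fluctuations inflate the signature (exact ties still
#' break toward fewer genes, then larger m; set `seTolerance = 0` for the
#' strict argmax). The full scan is stored in the signature provenance.
#'
#' @param weights named full-component gene weights, oriented
#'   positive-sensitive.
#' @param validationExpr normalized \linkS4class{ChemoExpr} (or matrix) of
#'   the independent validation cohort (disjoint from discovery).
#' @param validationAucs named numeric AUC per validation sample (>= 8).
#' @param drug drug name for the returned signature.
#' @param sdStep scan step in SD units.
#' @param mMax largest threshold scanned (default 3).
#' @param center gene-center validation rows before projection.
#' @param seTolerance parsimony tolerance in Fisher-z standard errors
#'   (default 1).
#' @return A \linkS4class{DrugSignature}.
#' @export
optimizeFeatureCount <- function(weights, validationExpr, validationAucs,
                                 drug = "drug", sdStep = 0.5, mMax = 3,
                                 center = TRUE, seTolerance = 1) {
  if (is.null(names(weights))) stop("weights must be named by gene")
  if (length(validationAucs) < 8L)
    stop("need at least 8 validation samples")
  sdw <- stats::sd(weights)
  mGrid <- seq(mMax, 0, by = -sdStep)
  trace <- list()
  seen <- character()
  for (m in mGrid) {
    genes <- names(weights)[abs(weights) > m * sdw]
    if (length(genes) == 0L) next  # skip empty candidate at large m
    key <- paste(sort(genes), collapse = "|")
    sig <- DrugSignature(drug, genes, weights[genes])
    rho <- if (key %in% seen) {
      trace[[which(vapply(trace, `[[`, character(1), "key") == key)[1]]]$rho
    } else {
      pr <- projectSignature(sig, validationExpr, minOverlap = 0,
                             center = center)
      v <- validateProjectionQuiet(sampleScores(pr), validationAucs)
      v$rho
    }
    seen <- c(seen, key)
    trace[[length(trace) + 1L]] <- list(m = m, nGenes = length(genes),
                                        rho = rho, key = key)
  }
  if (length(trace) == 0L)
    stop("all candidate gene sets were empty")
  tt <- data.frame(m = vapply(trace, `[[`, numeric(1), "m"),
                   nGenes = vapply(trace, `[[`, numeric(1), "nGenes"),
                   rho = vapply(trace, `[[`, numeric(1), "rho"))
  z <- atanh(pmin(abs(tt$rho), 1 - 1e-12))
  tol <- max(seTolerance / sqrt(length(validationAucs) - 3), 1e-12)
  cand <- which(z >= max(z) - tol)
  cand <- cand[order(tt$nGenes[cand], -tt$m[cand])]
  pick <- cand[1L]
  genes <- strsplit(trace[[pick]]$key, "|", fixed = TRUE)[[1L]]
  genes <- names(weights)[names(weights) %in% genes]  # original order
  DrugSignature(drug, genes, weights[genes],
                provenance = list(
                  optimization = tt[, c("m", "nGenes", "rho")],
                  mSelected = tt$m[pick], rhoSelected = tt$rho[pick],
                  sdStep = sdStep, validationN = length(validationAucs)))
}

# Spearman without the orientation warning (used inside the scan, where
# candidate orientation is fixed afterwards).
validateProjectionQuiet <- function(scores, response) {
  shared <- intersect(names(scores), names(response))
  s <- scores[shared]; r <- response[shared]
  if (stats::sd(s) < 1e-12) return(list(rho = 0, p = 1, n = length(shared)))
  list(rho = stats::cor(s, r, method = "spearman"), p = NA_real_,
       n = length(shared))
}
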