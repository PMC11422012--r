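#' @import methods
#' @import SummarizedExperiment
NULL

.NORM_STATES <- c("raw_counts", "tmm_log2", "external_normalized")

#' ChemoExpr: gene-by-sample expression with normalization state
#'
#' A thin extension of \linkS4class{SummarizedExperiment} carrying a single
#' `exprs` assay (genes in rows, samples in columns) and a normalization
#' state. `raw_counts` matrices must be non-negative and integral; normalized
#' matrices (`tmm_log2`, `external_normalized`) are the substrate of ICA and
#' signature projection.
#'
#' @slot normState one of `"raw_counts"`, `"tmm_log2"`,
#'   `"external_normalized"`.
#' @export
setClass("ChemoExpr",
  contains = "SummarizedExperiment",
  representation(normState = "character")
)

setValidity("ChemoExpr", function(object) {
  msg <- character()
  if (length(object@normState) != 1L || !object@normState %in% .NORM_STATES)
    msg <- c(msg, sprintf("normState must be one of: %s",
                          paste(.NORM_STATES, collapse = ", ")))
  m <- SummarizedExperiment::assay(object)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "gene and sample identifiers are required")
  else {
    if (anyDuplicated(rownames(m)))
      msg <- c(msg, sprintf("duplicate gene identifiers: %s",
        paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
    if (anyDuplicated(colnames(m)))
      msg <- c(msg, sprintf("duplicate sample identifiers: %s",
        paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  }
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must be finite")
  else if (identical(object@normState, "raw_counts") &&
           (any(m < 0) || any(abs(m - round(m)) > 1e-8)))
    msg <- c(msg, "raw_counts state requires non-negative integral values")
  if (length(msg)) msg else TRUE
})

#' Construct a ChemoExpr object
#'
#' @param values numeric genes x samples matrix with unique row and column
#'   names.
#' @param state normalization state of `values`.
#' @return A \linkS4class{ChemoExpr}.
#' @examples
#' m <- matrix(0:5, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ChemoExpr(m, "raw_counts")
#' @export
ChemoExpr <- function(values, state = c("external_normalized", "raw_counts",
                                        "tmm_log2")) {
  state <- match.arg(state)
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ChemoExpr", se, normState = state)
}

#' ICADecomposition: one cohort's ICA deconvolution
#'
#' Gene-contribution (source) and sample-contribution (mixing) matrices from
#' independent component analysis of a centered expression matrix. Columns of
#' `geneContrib` are scaled to unit variance; `geneContrib %*% sampleContrib`
#' reconstructs the row-centered input (up to the retained rank).
#'
#' @slot geneContrib genes x k source matrix.
#' @slot sampleContrib k x samples mixing matrix.
#' @slot k integer component count.
#' @slot seed integer seed used for the restarts.
#' @slot cohortId cohort label.
#' @export
setClass("ICADecomposition",
  representation(geneContrib = "matrix", sampleContrib = "matrix",
                 k = "integer", seed = "integer", cohortId = "character")
)

setValidity("ICADecomposition", function(object) {
  msg <- character()
  if (ncol(object@geneContrib) != object@k ||
      nrow(object@sampleContrib) != object@k)
    msg <- c(msg, "component count k inconsistent with matrix shapes")
  if (!all(is.finite(object@geneContrib)) ||
      !all(is.finite(object@sampleContrib)))
    msg <- c(msg, "contribution matrices must be finite")
  v <- apply(object@geneContrib, 2, stats::var)
  if (any(abs(v - 1) > 1e-6))
    msg <- c(msg, "geneContrib columns must have unit variance")
  if (length(msg)) msg else TRUE
})

#' DrugSignature: a drug's gene-weight chemosensitivity signature
#'
#' The central deliverable of the derivation pipeline: gene identifiers with
#' contribution weights, oriented so that a higher projection score means
#' greater predicted sensitivity (lower viability AUC).
#'
#' @slot drug drug name.
#' @slot geneIds character gene identifiers (unique).
#' @slot weights numeric per-gene weights (not all zero).
#' @slot provenance list of derivation metadata (component indices,
#'   correlation values, optimization trace, seeds).
#' @export
setClass("DrugSignature",
  representation(drug = "character", geneIds = "character",
                 weights = "numeric", provenance = "list")
)

setValidity("DrugSignature", function(object) {
  msg <- character()
  if (length(object@geneIds) == 0L)
    msg <- c(msg, "signature must contain at least one gene")
  if (length(object@geneIds) != length(object@weights))
    msg <- c(msg, "geneIds and weights lengths differ")
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, sprintf("duplicate genes: %s",
      paste(unique(object@geneIds[duplicated(object@geneIds)]),
            collapse = ", ")))
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  else if (all(object@weights == 0))
    msg <- c(msg, "weights must not all be zero")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugSignature
#'
#' @param drug drug name.
#' @param geneIds character vector of gene identifiers.
#' @param weights numeric weights, same length as `geneIds`.
#' @param provenance optional list of derivation metadata.
#' @return A \linkS4class{DrugSignature}.
#' @export
DrugSignature <- function(drug, geneIds, weights, provenance = list()) {
  new("DrugSignature", drug = as.character(drug),
      geneIds = as.character(geneIds),
      weights = stats::setNames(as.numeric(weights), geneIds),
      provenance = provenance)
}

#' ProjectionResult: per-sample signature scores
#'
#' @slot sampleScores named numeric score per sample.
#' @slot genesUsed signature genes found in the target matrix.
#' @slot genesMissing signature genes absent from the target matrix.
#' @slot overlapFraction |genesUsed| / signature size.
#' @export
setClass("ProjectionResult",
  representation(sampleScores = "numeric", genesUsed = "character",
                 genesMissing = "character", overlapFraction = "numeric")
)

setValidity("ProjectionResult", function(object) {
  msg <- character()
  if (any(!is.finite(object@sampleScores)))
    msg <- c(msg, "scores must be finite")
  tot <- length(object@genesUsed) + length(object@genesMissing)
  if (tot > 0 &&
      abs(object@overlapFraction - length(object@genesUsed) / tot) > 1e-12)
    msg <- c(msg, "overlapFraction inconsistent with gene lists")
  if (length(msg)) msg else TRUE
})
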