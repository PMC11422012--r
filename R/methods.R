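# Accessors and show methods for the S4 containers.

#' @rdname ChemoExpr-class
#' @export
setMethod("exprValues", "ChemoExpr", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname ChemoExpr-class
#' @export
setMethod("normState", "ChemoExpr", function(x) x@normState)

setMethod("show", "ChemoExpr", function(object) {
  cat(sprintf("ChemoExpr: %d genes x %d samples [%s]\n",
              nrow(object), ncol(object), object@normState))
})

#' @rdname ICADecomposition-class
#' @export
setMethod("geneContrib", "ICADecomposition", function(x) x@geneContrib)

#' @rdname ICADecomposition-class
#' @export
setMethod("sampleContrib", "ICADecomposition", function(x) x@sampleContrib)

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf("ICADecomposition: %d genes, %d samples, k = %d (cohort %s, seed %d)\n",
              nrow(object@geneContrib), ncol(object@sampleContrib),
              object@k, object@cohortId, object@seed))
})

#' @rdname DrugSignature-class
#' @export
setMethod("geneIds", "DrugSignature", function(x) x@geneIds)

#' @rdname DrugSignature-class
#' @export
setMethod("sigWeights", "DrugSignature", function(x) x@weights)

#' @rdname DrugSignature-class
#' @export
setMethod("drugName", "DrugSignature", function(x) x@drug)

#' @rdname DrugSignature-class
#' @export
setMethod("provenance", "DrugSignature", function(x) x@provenance)

#' @rdname DrugSignature-class
#' @param object a DrugSignature.
#' @export
setMethod("length", "DrugSignature", function(x) length(x@geneIds))

setMethod("show", "DrugSignature", function(object) {
  cat(sprintf("DrugSignature '%s': %d genes\n", object@drug,
              length(object@geneIds)))
  n <- min(5L, length(object@geneIds))
  cat(sprintf("  top |weight|: %s\n",
              paste(names(sort(-abs(object@weights)))[seq_len(n)],
                    collapse = ", ")))
})

#' @rdname ProjectionResult-class
#' @export
setMethod("sampleScores", "ProjectionResult", function(x) x@sampleScores)

#' @rdname ProjectionResult-class
#' @export
setMethod("overlapFraction", "ProjectionResult", function(x)
  x@overlapFraction)

#' @rdname ProjectionResult-class
#' @export
setMethod("genesUsed", "ProjectionResult", function(x) x@genesUsed)

#' @rdname ProjectionResult-class
#' @export
setMethod("genesMissing", "ProjectionResult", function(x) x@genesMissing)

setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf("ProjectionResult: %d samples scored, gene overlap %.1f%%\n",
              length(object@sampleScores), 100 * object@overlapFraction))
})
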