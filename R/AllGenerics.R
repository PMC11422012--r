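#' @rdname ChemoExpr-class
#' @param x a ChemoExpr, ICADecomposition, DrugSignature or ProjectionResult.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ChemoExpr-class
#' @export
setGeneric("normState", function(x) standardGeneric("normState"))

#' @rdname ICADecomposition-class
#' @param x an ICADecomposition.
#' @export
setGeneric("geneContrib", function(x) standardGeneric("geneContrib"))

#' @rdname ICADecomposition-class
#' @export
setGeneric("sampleContrib", function(x) standardGeneric("sampleContrib"))

#' @rdname DrugSignature-class
#' @param x a DrugSignature.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname DrugSignature-class
#' @export
setGeneric("sigWeights", function(x) standardGeneric("sigWeights"))

#' @rdname DrugSignature-class
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))

#' @rdname DrugSignature-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ProjectionResult-class
#' @param x a ProjectionResult.
#' @export
setGeneric("sampleScores", function(x) standardGeneric("sampleScores"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("overlapFraction", function(x) standardGeneric("overlapFraction"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("genesUsed", function(x) standardGeneric("genesUsed"))

#' @rdname ProjectionResult-class
#' @export
setGeneric("genesMissing", function(x) standardGeneric("genesMissing"))
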