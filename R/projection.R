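# Moore-Penrose pseudoinverse projection of a signature onto an expression
# matrix, and its validation against measured response.

#' Project a drug signature onto an expression matrix
#'
#' Weights and matrix are restricted to their shared genes; target rows are
#' gene-centered across samples (matching the centering ICA was run on,
#' disable with `center = FALSE`); the score vector is the cross-product of
#' the Moore-Penrose generalized inverse of the weight vector with the
#' expression matrix, which for a single component is the closed form
#' `t(w) %*% X / sum(w^2)` (the per-sample least-squares coefficient of X on
#' w). Higher score = more sensitive, by signature orientation.
#'
#' @param sig a \linkS4class{DrugSignature}.
#' @param x a normalized \linkS4class{ChemoExpr} or numeric matrix.
#' @param minOverlap minimum fraction of signature genes that must be
#'   present (default 0.80).
#' @param center gene-center the target rows first (default TRUE).
#' @return A \linkS4class{ProjectionResult}.
#' @export
projectSignature <- function(sig, x, minOverlap = 0.80, center = TRUE) {
  if (is(x, "ChemoExpr")) {
    if (identical(normState(x), "raw_counts"))
      stop("normalize counts before projection")
    m <- exprValues(x)
  } else m <- as.matrix(x)
  w <- sigWeights(sig)
  shared <- intersect(geneIds(sig), rownames(m))
  missing <- setdiff(geneIds(sig), shared)
  overlap <- length(shared) / length(geneIds(sig))
  if (overlap < minOverlap)
    stop(sprintf(
      "gene overlap %.2f below %.2f; missing: %s%s", overlap, minOverlap,
      paste(utils::head(missing, 10L), collapse = ", "),
      if (length(missing) > 10L) ", ..." else ""))
  Xs <- m[shared, , drop = FALSE]
  if (center) Xs <- Xs - rowMeans(Xs)
  ws <- w[shared]
  n2 <- sum(ws^2)
  if (n2 < 1e-300) stop("restricted weights have zero norm")
  scores <- drop(crossprod(ws, Xs)) / n2
  new("ProjectionResult", sampleScores = scores, genesUsed = shared,
      genesMissing = missing, overlapFraction = overlap)
}

#' Multi-component pseudoinverse projection
#'
#' General fallback for projecting several components at once:
#' `scores = ginv(W) %*% X` on the shared genes.
#'
#' @param W genes x components weight matrix with rownames.
#' @param x normalized \linkS4class{ChemoExpr} or matrix.
#' @param center gene-center target rows first.
#' @return components x samples score matrix.
#' @export
projectComponents <- function(W, x, center = TRUE) {
  m <- if (is(x, "ChemoExpr")) exprValues(x) else as.matrix(x)
  shared <- intersect(rownames(W), rownames(m))
  if (length(shared) == 0L) stop("no shared genes")
  Xs <- m[shared, , drop = FALSE]
  if (center) Xs <- Xs - rowMeans(Xs)
  MASS::ginv(W[shared, , drop = FALSE]) %*% Xs
}

#' Validate projected scores against measured response
#'
#' Spearman correlation between scores and response (viability AUC or POR);
#' exact p for small n without ties, asymptotic otherwise (stats::cor.test
#' convention). A warning is issued when rho > 0, since a correctly oriented
#' signature anticorrelates with AUC.
#'
#' @param result a \linkS4class{ProjectionResult} or named score vector.
#' @param response named numeric response per sample (lower = more
#'   sensitive).
#' @return list with `rho`, `p` and `n`.
#' @export
validateProjection <- function(result, response) {
  scores <- if (is(result, "ProjectionResult")) sampleScores(result)
            else result
  shared <- intersect(names(scores), names(response))
  if (length(shared) < 5L) stop("need at least 5 overlapping samples")
  s <- scores[shared]; r <- response[shared]
  if (stats::sd(s) < 1e-12)
    stop("constant scores; correlation undefined")
  ct <- suppressWarnings(stats::cor.test(s, r, method = "spearman"))
  if (ct$estimate > 0)
    warning("scores correlate positively with AUC; check signature orientation")
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
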