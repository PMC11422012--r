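# ICA deconvolution of an expression matrix into gene-contribution (source)
# and sample-contribution (mixing) matrices. FastICA with a symmetric
# fixed-point update and tanh (log-cosh) nonlinearity, restarted from
# several random rotations; sources here are gene-loading profiles, which
# for sparse planted programs are strongly leptokurtic.

#' Run ICA on a normalized expression matrix
#'
#' Rows (genes) are centered across samples, the matrix is reduced to `k`
#' principal directions, and a symmetric FastICA rotation is estimated from
#' `nRestarts` random orthonormal starts; the restart with the highest mean
#' absolute excess kurtosis of the gene contributions is kept. Components
#' are ordered by descending explained variance and signed so the gene with
#' the largest absolute contribution is positive, making the decomposition
#' deterministic given `(seed, nRestarts)`.
#'
#' @param x a normalized \linkS4class{ChemoExpr} (`tmm_log2` or
#'   `external_normalized`) or numeric matrix with dimnames.
#' @param k number of components; must satisfy `k < n_samples` (row
#'   centering caps the usable rank at `n_samples - 1`).
#' @param seed integer seed for the restarts.
#' @param nRestarts number of random restarts (default 10).
#' @param maxit,tol fixed-point iteration controls.
#' @param cohortId label stored on the result.
#' @return An \linkS4class{ICADecomposition}. Zero-variance genes are
#'   removed before decomposition.
#' @export
runICA <- function(x, k, seed = 1L, nRestarts = 10L, maxit = 200L,
                   tol = 1e-6, cohortId = "cohort") {
  if (is(x, "ChemoExpr")) {
    if (identical(normState(x), "raw_counts"))
      stop("normalize counts before ICA (tmm_log2 or external_normalized)")
    m <- exprValues(x)
  } else m <- as.matrix(x)
  ns <- ncol(m)
  if (k >= ns) stop(sprintf("k (%d) must be < number of samples (%d)", k, ns))
  if (k < 1L) stop("k must be >= 1")
  keep <- apply(m, 1L, stats::var) > 1e-12
  m <- m[keep, , drop = FALSE]
  ng <- nrow(m)
  if (k >= ng) stop("k must be < number of informative genes")
  mc <- m - rowMeans(m)
  sv <- svd(mc, nu = k, nv = k)
  if (sv$d[k] < 1e-9 * sv$d[1])
    stop("matrix rank below k; reduce the number of components")
  Z <- sv$u * sqrt(ng - 1)                      # whitened gene scores, var 1
  proj <- diag(sv$d[1:k], k) %*% t(sv$v) / sqrt(ng - 1)

  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      W0 <- matrix(stats::rnorm(k * k), k, k)
      dec <- svd(W0)
      W <- dec$u %*% t(dec$v)                   # random orthonormal start
      converged <- FALSE
      for (it in seq_len(maxit)) {
        S <- Z %*% t(W)
        G <- tanh(S)
        W1 <- crossprod(G, Z) / ng - diag(colMeans(1 - G^2), k) %*% W
        e <- eigen(tcrossprod(W1), symmetric = TRUE)
        W1 <- e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), k) %*%
          t(e$vectors) %*% W1
        delta <- max(abs(1 - abs(rowSums(W1 * W))))
        W <- W1
        if (delta < tol) { converged <- TRUE; break }
      }
      S <- Z %*% t(W)
      kurt <- mean(abs(colMeans(S^4) - 3))
      if (converged && (is.null(best) || kurt > best$kurt))
        best <- list(W = W, kurt = kurt)
    }
  })
  if (is.null(best))
    stop("ICA failed to converge from any restart")
  W <- best$W
  S <- Z %*% t(W)                               # genes x k, unit variance
  A <- W %*% proj                               # k x samples
  ev <- rowSums(A^2)                            # explained variance per comp
  o <- order(ev, decreasing = TRUE)
  S <- S[, o, drop = FALSE]
  A <- A[o, , drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(S[, j]))
    if (S[i, j] < 0) { S[, j] <- -S[, j]; A[j, ] <- -A[j, ] }
  }
  # re-standardize source columns to exact unit variance
  sdj <- apply(S, 2L, stats::sd)
  S <- sweep(S, 2L, sdj, "/")
  A <- sweep(A, 1L, sdj, "*")
  rownames(S) <- rownames(m)
  colnames(S) <- paste0("IC", seq_len(k))
  rownames(A) <- colnames(S)
  colnames(A) <- colnames(m)
  new("ICADecomposition", geneContrib = S, sampleContrib = A,
      k = as.integer(k), seed = as.integer(seed),
      cohortId = as.character(cohortId))
}
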