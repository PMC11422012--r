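# Cross-model component matching and response-component selection: the two
# criteria a signature component must satisfy (homologous between PDC and
# PDX; significantly correlated with PDC drug response).

#' Match ICA components between two model systems
#'
#' Greedy one-to-one matching by descending |Spearman rho| between the
#' sample contributions of the two decompositions across paired patients.
#' The matched partner component's sign alignment (the sign of rho) is
#' recorded; pairs below the homology threshold are discarded.
#'
#' @param pdc,pdx \linkS4class{ICADecomposition}s from the two cohorts.
#' @param pairing named character vector mapping PDC sample id to PDX sample
#'   id; defaults to identity over the shared sample ids.
#' @param threshold minimum |rho| for a retained match (default 0.5).
#' @return data.frame of class `componentMatches` with columns
#'   `pdc_component`, `pdx_component`, `rho`, `sign`.
#' @export
matchComponents <- function(pdc, pdx, pairing = NULL, threshold = 0.5) {
  Ac <- sampleContrib(pdc); Ax <- sampleContrib(pdx)
  if (is.null(pairing)) {
    shared <- intersect(colnames(Ac), colnames(Ax))
    pairing <- stats::setNames(shared, shared)
  }
  if (!all(names(pairing) %in% colnames(Ac)) ||
      !all(pairing %in% colnames(Ax)))
    stop("pairing references samples absent from a decomposition")
  if (length(pairing) < 3L) stop("need at least 3 paired patients")
  R <- stats::cor(t(Ac[, names(pairing), drop = FALSE]),
                  t(Ax[, pairing, drop = FALSE]), method = "spearman")
  out <- list()
  while (TRUE) {
    i <- which.max(abs(R))
    if (length(i) == 0L || !is.finite(R[i]) || abs(R[i]) < threshold) break
    rc <- arrayInd(i, dim(R))
    out[[length(out) + 1L]] <- data.frame(
      pdc_component = rc[1], pdx_component = rc[2],
      rho = R[rc[1], rc[2]], sign = if (R[rc[1], rc[2]] < 0) -1 else 1)
    R[rc[1], ] <- NA
    R[, rc[2]] <- NA
    if (all(is.na(R))) break
  }
  matches <- if (length(out)) do.call(rbind, out) else
    data.frame(pdc_component = integer(), pdx_component = integer(),
               rho = numeric(), sign = numeric())
  class(matches) <- c("componentMatches", "data.frame")
  matches
}

#' Select the response component among homologous matches
#'
#' For each retained PDC/PDX match, the PDC component's sample contribution
#' is tested for Spearman correlation with the discovery AUCs, and the
#' match with maximum |rho| is the candidate. Because several homologous
#' components are screened, significance is assessed family-wise: the
#' default `"maxT"` adjustment compares the observed maximal |rho| with its
#' AUC-permutation null distribution (Westfall-Young), so a permuted-AUC
#' negative control passes the filter at rate ~`alpha` regardless of the
#' number of candidates; `"bonferroni"` and `"none"` are also available.
#' The selected component is oriented so that higher sample contribution
#' corresponds to lower AUC (greater sensitivity).
#'
#' @param matches a `componentMatches` data.frame.
#' @param pdc the PDC \linkS4class{ICADecomposition}.
#' @param aucs named numeric AUC per discovery sample.
#' @param alpha significance level (default 0.05).
#' @param adjust multiplicity handling across candidate matches.
#' @param nPerm permutations for the maxT null (default 999).
#' @param permSeed seed for the permutation draw.
#' @return list of class `responseComponent`: `component` (PDC index),
#'   `pdxComponent`, `rho`, `p` (adjusted), `orientation` (+-1 applied),
#'   oriented `weights` (named gene contributions) and the candidate
#'   `table` with per-component unadjusted p-values.
#' @export
selectResponseComponent <- function(matches, pdc, aucs, alpha = 0.05,
                                    adjust = c("maxT", "bonferroni", "none"),
                                    nPerm = 999L, permSeed = 0L) {
  adjust <- match.arg(adjust)
  if (nrow(matches) == 0L)
    stop("no response component: no homologous matches to test")
  A <- sampleContrib(pdc)
  ids <- names(aucs)
  if (!all(ids %in% colnames(A)))
    stop("aucs reference samples absent from the decomposition")
  res <- lapply(seq_len(nrow(matches)), function(i) {
    v <- A[matches$pdc_component[i], ids]
    ct <- suppressWarnings(
      stats::cor.test(v, aucs, method = "spearman"))
    data.frame(pdc_component = matches$pdc_component[i],
               pdx_component = matches$pdx_component[i],
               rho = unname(ct$estimate), p = ct$p.value)
  })
  tab <- do.call(rbind, res)
  if (adjust == "maxT") {
    # permutation null of max |Spearman| across the candidate components
    Rc <- t(apply(A[tab$pdc_component, ids, drop = FALSE], 1L, rank))
    Rc <- Rc - rowMeans(Rc)
    Rc <- Rc / sqrt(rowSums(Rc^2))
    ra <- rank(aucs)
    ra <- (ra - mean(ra)) / sqrt(sum((ra - mean(ra))^2))
    obs <- max(abs(tab$rho))
    nullMax <- withSeed(permSeed, {
      P <- vapply(seq_len(nPerm), function(b) sample(ra),
                  numeric(length(ra)))
      apply(abs(Rc %*% P), 2L, max)
    })
    pFW <- (1 + sum(nullMax >= obs - 1e-12)) / (nPerm + 1)
    if (pFW >= alpha)
      stop("no response component: no match correlates with AUC at alpha")
    pick <- which.max(abs(tab$rho))
    tab$pAdjusted <- vapply(abs(tab$rho), function(r)
      (1 + sum(nullMax >= r - 1e-12)) / (nPerm + 1), numeric(1))
  } else {
    thr <- if (adjust == "bonferroni") alpha / nrow(tab) else alpha
    sig <- which(tab$p < thr)
    if (length(sig) == 0L)
      stop("no response component: no match correlates with AUC at alpha")
    pick <- sig[which.max(abs(tab$rho[sig]))]
    pFW <- tab$p[pick]
  }
  orientation <- if (tab$rho[pick] > 0) -1 else 1
  w <- orientation * geneContrib(pdc)[, tab$pdc_component[pick]]
  structure(list(component = tab$pdc_component[pick],
                 pdxComponent = tab$pdx_component[pick],
                 rho = tab$rho[pick], p = pFW,
                 orientation = orientation, weights = w, table = tab,
                 alpha = alpha, adjust = adjust),
            class = "responseComponent")
}
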