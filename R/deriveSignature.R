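# End-to-end signature derivation: discovery selection -> paired ICA ->
# cross-model matching -> response-component selection -> feature-count
# optimization.

#' Derive a drug chemosensitivity signature
#'
#' Orchestrates the full derivation pipeline. The discovery PDCs in the AUC
#' percentile bands [P10, P25] and [P75, P90] are selected (6 + 6); ICA is
#' run on the selected PDC and the same patients' PDX profiles; components
#' homologous across the two model systems are matched; the match whose PDC
#' sample contribution significantly correlates with AUC is selected and
#' oriented positive-sensitive; and the feature count is optimized on an
#' independent PDC validation cohort. PDX POR correlation with the selected
#' component is recorded in provenance but is not a selection criterion.
#'
#' @param pdcExpr,pdxExpr normalized \linkS4class{ChemoExpr} matrices for
#'   the discovery PDC pool and paired PDX cohort; columns are patient ids,
#'   shared between the two.
#' @param pdcAucs named viability AUC per PDC pool sample.
#' @param pdxPors optional named POR per PDX (logged only).
#' @param validationExpr,validationAucs independent PDC validation cohort.
#' @param config a \code{\link{runConfig}}.
#' @param drug drug name.
#' @return A \linkS4class{DrugSignature} with complete provenance.
#' @export
deriveSignature <- function(pdcExpr, pdxExpr, pdcAucs, pdxPors = NULL,
                            validationExpr, validationAucs,
                            config = runConfig(), drug = "drug") {
  sel <- stageCall("select_discovery_samples",
                   selectDiscoverySamples(pdcAucs))
  ids <- c(sel$sensitive, sel$resistant)
  stageCall("subset_cohorts", {
    if (!all(ids %in% colnames(pdcExpr)))
      stop("selected samples missing from PDC expression")
    if (!all(ids %in% colnames(pdxExpr)))
      stop("selected patients missing from paired PDX expression")
  })
  k <- min(config$nComponents, length(ids) - 1L)
  icaPdc <- stageCall("run_ica_pdc",
    runICA(pdcExpr[, ids], k = k, seed = config$seed,
           nRestarts = config$nRestarts, cohortId = "PDC"))
  icaPdx <- stageCall("run_ica_pdx",
    runICA(pdxExpr[, ids], k = k, seed = config$seed + 1L,
           nRestarts = config$nRestarts, cohortId = "PDX"))
  matches <- stageCall("match_components",
    matchComponents(icaPdc, icaPdx,
                    pairing = stats::setNames(ids, ids),
                    threshold = config$homologyThreshold))
  rc <- stageCall("select_response_component",
    selectResponseComponent(matches, icaPdc, pdcAucs[ids],
                            alpha = config$alpha,
                            permSeed = config$seed + 2L))
  porRho <- NA_real_
  if (!is.null(pdxPors)) {
    shared <- intersect(ids, names(pdxPors))
    if (length(shared) >= 3L) {
      vx <- sampleContrib(icaPdx)[rc$pdxComponent, shared] *
        matches$sign[matches$pdc_component == rc$component] *
        rc$orientation
      porRho <- stats::cor(vx, pdxPors[shared], method = "spearman")
    }
  }
  sig <- stageCall("optimize_feature_count",
    optimizeFeatureCount(rc$weights, validationExpr, validationAucs,
                         drug = drug, sdStep = config$sdStep))
  prov <- provenance(sig)
  prov$discovery <- sel[c("sensitive", "resistant")]
  prov$k <- k
  prov$seed <- config$seed
  prov$component <- rc$component
  prov$pdxComponent <- rc$pdxComponent
  prov$matchTable <- as.data.frame(matches)
  prov$responseRho <- rc$rho
  prov$responseP <- rc$p
  prov$orientation <- rc$orientation
  prov$pdxPorRho <- porRho
  initialize(sig, provenance = prov)
}
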