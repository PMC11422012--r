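# Run configuration: defaults, validation, YAML loading.

#' Build a run configuration
#'
#' Central knobs of the derivation pipeline. Signature sizes default to the
#' published per-drug feature counts (5FU 39, oxaliplatin 277, irinotecan
#' 25); on synthetic data the derived size instead tracks the planted
#' support, so these are carried as configuration metadata only.
#'
#' @param seed integer seed, recorded in every output.
#' @param nComponents ICA component count (capped at n_samples - 1 during
#'   derivation).
#' @param signatureSizes named integer vector of per-drug target sizes.
#' @param minGroupProportion minimum fraction of patients per cutpoint group,
#'   in (0, 0.5).
#' @param alpha two-sided significance level.
#' @param minGeneOverlap minimum signature/matrix gene overlap for
#'   projection.
#' @param nRestarts ICA restarts.
#' @param homologyThreshold minimum |Spearman rho| for a PDC/PDX component
#'   match.
#' @param sdStep step (in SDs) of the feature-count scan; 1 reproduces the
#'   coarse one-SD-interval scan, 0.5 (default) refines it.
#' @param paths optional named list of input/output paths.
#' @return A list of class `chemosigConfig`.
#' @export
runConfig <- function(seed = 1L, nComponents = 12L,
                      signatureSizes = c("5FU" = 39L, oxaliplatin = 277L,
                                         irinotecan = 25L),
                      minGroupProportion = 0.10, alpha = 0.05,
                      minGeneOverlap = 0.80, nRestarts = 10L,
                      homologyThreshold = 0.5, sdStep = 0.5,
                      paths = list()) {
  cfg <- list(seed = as.integer(seed), nComponents = as.integer(nComponents),
              signatureSizes = signatureSizes,
              minGroupProportion = minGroupProportion, alpha = alpha,
              minGeneOverlap = minGeneOverlap,
              nRestarts = as.integer(nRestarts),
              homologyThreshold = homologyThreshold, sdStep = sdStep,
              paths = paths)
  class(cfg) <- "chemosigConfig"
  validateConfig(cfg)
}

#' @rdname runConfig
#' @param cfg a `chemosigConfig` list.
#' @export
validateConfig <- function(cfg) {
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("seed must be a single integer")
  if (cfg$minGroupProportion <= 0 || cfg$minGroupProportion >= 0.5)
    stop("minGroupProportion must be in (0, 0.5)")
  if (any(cfg$signatureSizes <= 0)) stop("signature sizes must be positive")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$minGeneOverlap <= 0 || cfg$minGeneOverlap > 1)
    stop("minGeneOverlap must be in (0, 1]")
  if (cfg$nComponents < 1L) stop("nComponents must be >= 1")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Unknown fields are kept under `paths`; known fields override
#' \code{\link{runConfig}} defaults.
#'
#' @param path YAML file path.
#' @return A validated `chemosigConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- intersect(names(y), names(formals(runConfig)))
  cfg <- do.call(runConfig, y[known])
  cfg$paths <- utils::modifyList(cfg$paths, y[setdiff(names(y), known)])
  cfg
}
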