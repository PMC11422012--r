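# Synthetic-data generator: paired PDC/PDX expression with planted latent
# response programs, dose-response panels, PDX growth curves, and a
# clinical cohort with score-dependent survival. Every dataset ships its
# ground truth, so each pipeline stage is verifiable by parameter recovery.
# All generators are pure functions of (spec, seed).

#' Simulation specification
#'
#' Defaults define the study conditions the pipeline is validated under:
#' a discovery pool of 40 paired PDC/PDX patients (from which the 12
#' discovery patients in the AUC percentile bands are selected), a
#' 30-sample independent PDC validation cohort plus a 30-sample held-out
#' test cohort, and a 170-patient clinical cohort with a 56.3% mFFX arm.
#' Planted per-drug supports default to the published signature sizes
#' (39/277/25). `effectRho` is the target |Spearman| between a drug's
#' latent and its AUC. `hazardBetaPerDrug` is the mFFX-arm log-hazard per
#' sensitive-drug label, default `log(0.35)` mirroring the printed
#' univariate hazard ratios; signature effects are absent in the GEM arm.
#'
#' @param seed integer master seed.
#' @param nGenes number of genes.
#' @param nDiscoveryPool paired PDC/PDX patients in the discovery pool.
#' @param nValidationPdc,nTestPdc independent PDC cohort sizes.
#' @param nClinical clinical cohort size.
#' @param nLatent latent programs (first 3 are the drug programs).
#' @param supportSizes named planted support size per drug.
#' @param effectRho target |Spearman(latent, AUC)| in (0, 1].
#' @param noiseSd gene-level log2 noise SD.
#' @param modelNoiseSd SD of the model-system (PDC vs PDX) latent noise.
#' @param signalWeight,backgroundWeight planted weight magnitudes (log2
#'   units per latent SD).
#' @param backgroundSupport genes per non-drug background program.
#' @param supportOverlap fraction of each drug support shared with the
#'   next drug's (0 = disjoint).
#' @param porGamma strength of the growth-inhibition link between a drug's
#'   latent and the PDX treated arm (0 = null-effect drug).
#' @param mffxFraction fraction of clinical patients on mFFX.
#' @param hazardBetaPerDrug per-sensitive-drug log-hazard in the mFFX arm.
#' @param osMedianBaseline,gemMedianBaseline,weibullShape OS Weibull
#'   baselines (months): mFFX zero-sensitive median and GEM median.
#' @param pfsMedianBaseline,pfsGemMedianBaseline PFS baselines (months).
#' @param censoringMean mean of the exponential censoring time (months).
#' @param orrIntercept,orrSlope logit-linear objective-response model in
#'   the sensitive-drug count (mFFX arm).
#' @return list of class `simulationSpec`.
#' @export
simulationSpec <- function(seed = 1L, nGenes = 2000L, nDiscoveryPool = 40L,
                           nValidationPdc = 30L, nTestPdc = 30L,
                           nClinical = 170L, nLatent = 6L,
                           supportSizes = c("5FU" = 39L, oxaliplatin = 277L,
                                            irinotecan = 25L),
                           effectRho = 0.8, noiseSd = 0.25,
                           modelNoiseSd = 0.3, signalWeight = 2,
                           backgroundWeight = 0.8, backgroundSupport = 100L,
                           supportOverlap = 0, porGamma = 1.2,
                           mffxFraction = 0.563,
                           hazardBetaPerDrug = log(0.35),
                           osMedianBaseline = 7.6, gemMedianBaseline = 4.7,
                           weibullShape = 1.1, pfsMedianBaseline = 3.6,
                           pfsGemMedianBaseline = 2.4, censoringMean = 72,
                           orrIntercept = -2.5, orrSlope = 1.0) {
  spec <- as.list(environment())
  spec$supportSizes <- unlist(spec$supportSizes)  # YAML gives named lists
  if (any(spec$supportSizes <= 0)) stop("support sizes must be positive")
  if (spec$effectRho <= 0 || spec$effectRho > 1)
    stop("effectRho must be in (0, 1]")
  if (spec$nLatent < length(spec$supportSizes))
    stop("need at least one latent per drug")
  if (sum(spec$supportSizes) + spec$backgroundSupport > spec$nGenes)
    stop("planted supports exceed the number of genes")
  class(spec) <- "simulationSpec"
  spec
}

.latentNames <- function(spec)
  c(names(spec$supportSizes),
    paste0("bg", seq_len(spec$nLatent - length(spec$supportSizes))))

# Draw a cohort latent matrix (nLatent x n, unit-variance Laplace).
.drawLatents <- function(spec, n, ids) {
  Z <- matrix(rlaplace(spec$nLatent * n), spec$nLatent, n,
              dimnames = list(.latentNames(spec), ids))
  Z
}

# Counts from latents: log2 mean = mu + W z + noise, Poisson sampling with
# per-sample library-size factors so the TMM path is exercised.
.countsFromLatents <- function(truth, Z, spec, ids) {
  n <- ncol(Z)
  logmu <- truth$mu + truth$W %*% Z +
    matrix(stats::rnorm(spec$nGenes * n, sd = spec$noiseSd), spec$nGenes, n)
  libf <- stats::runif(n, 0.7, 1.4)
  lam <- sweep(2^logmu, 2L, libf, "*")
  counts <- matrix(stats::rpois(length(lam), lam), spec$nGenes, n,
                   dimnames = list(rownames(truth$W), ids))
  counts
}

#' Simulate paired PDC/PDX expression with planted response programs
#'
#' Per pool patient, one latent vector is drawn (unit-variance Laplace, so
#' the non-Gaussianity ICA requires holds by construction) and shared by
#' that patient's PDC and PDX profiles with independent model-system noise.
#' Expression is a planted-weight outer product over each program's gene
#' support plus background, exponentiated and Poisson-sampled into counts.
#' Independent validation and held-out test PDC cohorts are generated from
#' their own patients.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @return list with `pdc`, `pdx`, `validation`, `test` (raw-count
#'   \linkS4class{ChemoExpr}s) and `truth` (planted supports/weights,
#'   per-cohort latents, gene baselines, spec).
#' @export
simulatePairedExpression <- function(spec = simulationSpec()) {
  withSeed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$nGenes))
    drugs <- names(spec$supportSizes)
    nBg <- spec$nLatent - length(drugs)
    free <- genes
    supports <- list()
    prev <- character()
    for (d in drugs) {
      nd <- spec$supportSizes[[d]]
      nShared <- min(round(spec$supportOverlap * nd), length(prev))
      sel <- c(if (nShared > 0) sample(prev, nShared),
               sample(free, nd - nShared))
      supports[[d]] <- sel
      free <- setdiff(free, sel)
      prev <- sel
    }
    W <- matrix(0, spec$nGenes, spec$nLatent,
                dimnames = list(genes, .latentNames(spec)))
    weights <- list()
    for (d in drugs) {
      w <- spec$signalWeight * stats::runif(length(supports[[d]]), 0.8, 1.2) *
        sample(c(-1, 1), length(supports[[d]]), replace = TRUE)
      W[supports[[d]], d] <- w
      weights[[d]] <- stats::setNames(w, supports[[d]])
    }
    for (b in seq_len(nBg)) {
      sel <- sample(free, min(spec$backgroundSupport, length(free)))
      W[sel, length(drugs) + b] <- spec$backgroundWeight *
        stats::runif(length(sel), 0.8, 1.2) *
        sample(c(-1, 1), length(sel), replace = TRUE)
    }
    mu <- stats::rnorm(spec$nGenes, mean = 6, sd = 1.5)
    truth <- list(W = W, mu = mu, supports = supports, weights = weights,
                  spec = spec, seed = spec$seed)

    poolIds <- sprintf("P%02d", seq_len(spec$nDiscoveryPool))
    valIds <- sprintf("V%02d", seq_len(spec$nValidationPdc))
    testIds <- sprintf("T%02d", seq_len(spec$nTestPdc))
    Zpat <- .drawLatents(spec, spec$nDiscoveryPool, poolIds)
    noiseM <- function(Z) Z + matrix(
      stats::rnorm(length(Z), sd = spec$modelNoiseSd), nrow(Z), ncol(Z),
      dimnames = dimnames(Z))
    Zpdc <- noiseM(Zpat)
    Zpdx <- noiseM(Zpat)
    Zval <- noiseM(.drawLatents(spec, spec$nValidationPdc, valIds))
    Ztest <- noiseM(.drawLatents(spec, spec$nTestPdc, testIds))
    truth$latents <- list(patient = Zpat, pdc = Zpdc, pdx = Zpdx,
                          validation = Zval, test = Ztest)
    out <- list(
      pdc = ChemoExpr(.countsFromLatents(truth, Zpdc, spec, poolIds),
                      "raw_counts"),
      pdx = ChemoExpr(.countsFromLatents(truth, Zpdx, spec, poolIds),
                      "raw_counts"),
      validation = ChemoExpr(.countsFromLatents(truth, Zval, spec, valIds),
                             "raw_counts"),
      test = ChemoExpr(.countsFromLatents(truth, Ztest, spec, testIds),
                       "raw_counts"),
      truth = truth)
    out
  })
}

# AUC targets from a latent row via the Gaussian copula: normal scores of
# the latent are mixed with independent noise at the Pearson coefficient
# 2*sin(rho*pi/6) that yields the requested Spearman, then mapped
# monotonically into [0.15, 0.85]. Sensitive (high latent) => low AUC.
.aucTargets <- function(z, effectRho) {
  n <- length(z)
  g <- stats::qnorm((rank(z) - 0.5) / n)
  r <- 2 * sin(effectRho * pi / 6)
  s <- -(r * g) + sqrt(1 - r^2) * stats::rnorm(n)
  stats::setNames(0.15 + 0.7 * stats::plogis(1.2 * s), names(z))
}

# Solve the 4PL log10-EC50 whose range-normalized AUC hits `target`.
.ec50ForAuc <- function(target, xg, upper = 1, lower = 0.05, hill = 1.3) {
  f <- function(le)
    trapz(xg, .fourPL(xg, upper, lower, le, hill)) / (max(xg) - min(xg)) -
    target
  stats::uniroot(f, c(min(xg) - 6, max(xg) + 6), tol = 1e-8)$root
}

#' Simulate drug-response readouts from planted latents
#'
#' PDC/validation/test cohorts receive per-model dose-response viability
#' panels (9 log-spaced doses from 1 nmol/L to 1 mmol/L, 3 replicates)
#' whose underlying 4PL AUC is a monotone noisy function of the planted
#' latent reaching Spearman ~ `effectRho`; pool PDXs receive logistic
#' growth curves (control and treated arms) whose treated plateau is
#' suppressed by the latent via `porGamma` (0 gives identical-distribution
#' arms and POR ~ 1).
#'
#' @param truth ground truth from \code{\link{simulatePairedExpression}}.
#' @param spec the same \code{\link{simulationSpec}}.
#' @param drugs drugs to simulate (default: all planted).
#' @param cohorts expression cohorts receiving viability panels.
#' @param growthDrugs drugs receiving PDX growth curves (default: first
#'   drug only; growth data are per-drug expensive).
#' @return list with `panels` (cohort -> drug -> named list of
#'   `doseResponsePanel`s), `growthCurves` (drug -> pdx -> control/treated
#'   `growthCurveSet`s), `aucTargets`, `porTargets`.
#' @export
simulateResponse <- function(truth, spec = truth$spec,
                             drugs = names(spec$supportSizes),
                             cohorts = c("pdc", "validation", "test"),
                             growthDrugs = drugs[1L]) {
  withSeed(spec$seed + 1L, {
    xg <- seq(-9, -3, length.out = 201L)
    doses <- 10^seq(-9, -3, length.out = 9L)
    panels <- list(); aucTargets <- list()
    for (co in cohorts) {
      Z <- truth$latents[[co]]
      panels[[co]] <- list(); aucTargets[[co]] <- list()
      for (d in drugs) {
        tg <- .aucTargets(Z[d, ], spec$effectRho)
        aucTargets[[co]][[d]] <- tg
        panels[[co]][[d]] <- lapply(stats::setNames(names(tg), names(tg)),
          function(id) {
            le <- .ec50ForAuc(tg[[id]], xg)
            v <- rep(.fourPL(log10(doses), 1, 0.05, le, 1.3), each = 3L)
            v <- pmax(v + stats::rnorm(length(v), sd = 0.05), 0)
            doseResponsePanel(rep(doses, each = 3L), v, modelId = id,
                              drug = d)
          })
      }
    }
    growth <- list(); porTargets <- list()
    days <- seq(0, 60, by = 4)
    Zx <- truth$latents$pdx
    for (d in growthDrugs) {
      growth[[d]] <- list()
      kap <- pmin(2 * stats::plogis(-spec$porGamma * Zx[d, ]), 1.3)
      porTargets[[d]] <- kap
      for (id in colnames(Zx)) {
        Vmax <- 1500 * stats::runif(1, 0.85, 1.15)
        k <- 0.1 * stats::runif(1, 0.9, 1.1)
        t0 <- log(Vmax / 200 - 1) / k
        mkArm <- function(mult, arm) {
          obs <- do.call(rbind, lapply(1:6, function(mi) {
            v <- mult * Vmax / (1 + exp(-k * (days - t0))) *
              exp(stats::rnorm(length(days), sd = 0.08))
            data.frame(mouse = paste0("m", mi), day = days, volume = v)
          }))
          growthCurveSet(obs, pdxId = id, arm = arm)
        }
        growth[[d]][[id]] <- list(control = mkArm(1, "control"),
                                  treated = mkArm(kap[[id]], "treated"))
      }
    }
    list(panels = panels, growthCurves = growth, aucTargets = aucTargets,
         porTargets = porTargets)
  })
}

#' Measure viability AUCs for a cohort's panels
#'
#' Fits each panel's 4PL and integrates, returning the named AUC vector the
#' derivation pipeline consumes.
#'
#' @param panels named list of `doseResponsePanel`s (one cohort x drug).
#' @return named numeric AUC per model.
#' @export
panelAucs <- function(panels) {
  vapply(panels, function(p)
    viabilityAUC(fitDoseResponse(p))$value, numeric(1))
}

#' Measure PORs from simulated growth curves
#'
#' @param growth one drug's growth-curve list (pdx -> control/treated).
#' @param method passed to \code{\link{por}}.
#' @return named numeric POR per PDX.
#' @export
growthPors <- function(growth, method = "fitted") {
  vapply(growth, function(g)
    por(g$treated, g$control, method = method)$value, numeric(1))
}

#' Simulate a clinical cohort with score-dependent survival
#'
#' Two treatment arms (mFFX fraction per spec); per patient, planted drug
#' latents define binary sensitivity labels (latent > 0). In the mFFX arm
#' only, the Weibull OS/PFS log-hazard is `hazardBetaPerDrug` times the
#' sensitive-drug count (the arm-exclusive effect structure); the GEM arm
#' has its own (worse) baseline and no signature effect. Objective response
#' is Bernoulli with logit linear in the count (mFFX arm); the PurIST-like
#' label is correlated with the second and third drug latents. Censoring is
#' independent exponential.
#'
#' @param truth ground truth from \code{\link{simulatePairedExpression}}
#'   (supplies the planted gene programs).
#' @param spec the same \code{\link{simulationSpec}}.
#' @return list with `expression` (raw-count \linkS4class{ChemoExpr}),
#'   `clinical` (data.frame: id, arm, os/pfs, response, purist, age, sex)
#'   and `truth` (latents, labels, counts).
#' @export
simulateClinicalCohort <- function(truth, spec = truth$spec) {
  withSeed(spec$seed + 2L, {
    n <- spec$nClinical
    ids <- sprintf("C%03d", seq_len(n))
    Z <- .drawLatents(spec, n, ids)
    counts <- .countsFromLatents(truth, Z, spec, ids)
    drugs <- names(spec$supportSizes)
    sens <- Z[drugs, , drop = FALSE] > 0
    cnt <- colSums(sens)
    arm <- ifelse(stats::runif(n) < spec$mffxFraction, "mFFX", "GEM")
    if (all(arm == "mFFX")) arm[1] <- "GEM"
    if (all(arm == "GEM")) arm[1] <- "mFFX"
    a <- spec$weibullShape
    simT <- function(mffxMed, gemMed) {
      scale0 <- mffxMed / log(2)^(1 / a)
      lp <- ifelse(arm == "mFFX", spec$hazardBetaPerDrug * cnt,
                   a * log(mffxMed / gemMed))
      scale0 * (-log(stats::runif(n)) / exp(lp))^(1 / a)
    }
    osT <- simT(spec$osMedianBaseline, spec$gemMedianBaseline)
    pfsT <- simT(spec$pfsMedianBaseline, spec$pfsGemMedianBaseline)
    cens <- pmin(stats::rexp(n, 1 / spec$censoringMean), 96)
    cens2 <- pmin(stats::rexp(n, 1 / spec$censoringMean), 96)
    pResp <- stats::plogis(spec$orrIntercept +
                           ifelse(arm == "mFFX", spec$orrSlope * cnt, 0))
    responder <- stats::runif(n) < pResp
    response <- ifelse(responder,
                       ifelse(stats::runif(n) < 0.2, "CR", "PR"),
                       ifelse(stats::runif(n) < 0.5, "SD", "PD"))
    purist <- ifelse(
      stats::runif(n) < stats::plogis(0.9 * (Z[drugs[2], ] + Z[drugs[3], ]) /
                                        sqrt(2)),
      "classical", "basal-like")
    clinical <- data.frame(
      id = ids, arm = arm,
      os_time = pmax(pmin(osT, cens), 1e-3),
      os_event = as.integer(osT <= cens),
      pfs_time = pmax(pmin(pfsT, cens2), 1e-3),
      pfs_event = as.integer(pfsT <= cens2),
      response = response, purist = purist,
      age = round(stats::rnorm(n, 65, 8), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      row.names = NULL, stringsAsFactors = FALSE)
    list(expression = ChemoExpr(counts, "raw_counts"), clinical = clinical,
         truth = list(latents = Z, sensitive = sens, counts = cnt,
                      arm = arm))
  })
}

#' Simulate the complete study
#'
#' Convenience wrapper: paired expression + response readouts + clinical
#' cohort, with the combined ground truth.
#'
#' @param spec a \code{\link{simulationSpec}}.
#' @param growthDrugs drugs receiving PDX growth curves.
#' @return nested list with `expression`, `response`, `clinical`, `truth`.
#' @export
simulateStudy <- function(spec = simulationSpec(),
                          growthDrugs = names(spec$supportSizes)[1L]) {
  ex <- simulatePairedExpression(spec)
  resp <- simulateResponse(ex$truth, spec, growthDrugs = growthDrugs)
  clin <- simulateClinicalCohort(ex$truth, spec)
  list(expression = ex[c("pdc", "pdx", "validation", "test")],
       response = resp, clinical = clin,
       truth = c(ex$truth, list(clinical = clin$truth,
                                aucTargets = resp$aucTargets,
                                porTargets = resp$porTargets)))
}

#' Serialize ground truth to JSON
#'
#' Writes planted supports/weights, per-cohort latents and clinical labels
#' so that grading of a simulated dataset never reads pipeline internals.
#'
#' @param truth a ground-truth list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  keep <- list(
    seed = truth$seed,
    supports = truth$supports,
    weights = truth$weights,
    latents = lapply(truth$latents, function(m) as.data.frame(t(m))),
    clinical = if (!is.null(truth$clinical))
      list(sensitive = as.data.frame(t(truth$clinical$sensitive)),
           counts = truth$clinical$counts, arm = truth$clinical$arm),
    aucTargets = truth$aucTargets,
    porTargets = truth$porTargets)
  jsonlite::write_json(keep, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
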