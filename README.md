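# chemosig

Drug-specific transcriptomic chemosensitivity signatures from
patient-derived tumor models, with clinical-validation statistics.

## The problem

Modified FOLFIRINOX (mFFX: 5-fluorouracil, oxaliplatin, irinotecan plus
leucovorin) is a standard combination chemotherapy for advanced pancreatic
ductal adenocarcinoma, but its toxicity restricts it to fit patients, and
there is no rational way to decide which of its cytotoxic components an
individual tumor will respond to. One line of attack derives a
transcriptomic signature for **each** drug from panels of patient-derived
models — primary cell cultures (PDC), organoids (PDO) and xenografts (PDX),
which expose nearly pure epithelial tumor cells to each drug — and then
scores patient tumors by projecting those signatures onto their expression
profiles.

chemosig implements that entire pipeline as a tested, reusable R package
for computational biologists working on chemo-response stratification:

- **TMM/log2 normalization** of count matrices (edgeR's estimator behind a
  validated surface);
- **drug-response scoring**: 4-parameter-logistic dose–response fits and
  range-normalized viability AUC for PDC/PDO; logistic tumor growth-curve
  fits and the AUC-ratio *percentage of resistance*
  (POR = AUC_treated / AUC_control) for PDX;
- **signature extraction**: discovery-cohort selection by AUC percentile
  bands ([P10, P25] and [P75, P90], 6 + 6 of a model pool), ICA
  deconvolution of expression into gene-contribution and
  sample-contribution matrices (X ≈ S·A), greedy cross-model component
  matching by Spearman correlation over shared patients, family-wise
  (permutation maxT) selection of the AUC-correlated component, and
  SD-interval feature-count optimization on an independent cohort;
- **projection scoring** via the Moore–Penrose pseudoinverse: for one
  component, score = wᵀX / ‖w‖², oriented so higher score = more
  sensitive;
- **clinical statistics**: Kaplan–Meier, log-rank, maximally selected
  survival cutpoints (with the Lausen–Schumacher corrected p alongside the
  scan minimum), Efron-tie Cox models with separation diagnostics,
  IPTW-adjusted KM curves, exact binomial ORR with Clopper–Pearson CI,
  chi-square, and 0–3 sensitive-drug-count combination profiles;
- **a synthetic-data generator** that plants known response programs in
  paired PDC/PDX expression, dose–response panels, growth curves and a
  two-arm clinical cohort with score-dependent Weibull survival — so every
  stage of the pipeline is validated by parameter recovery against ground
  truth.

The methods vignette (`vignettes/chemosig-methods.Rmd`) documents the
models, parameter choices and numerical conventions in detail.

## Worked example

Simulate a study with planted ground truth, derive the irinotecan
signature, and validate it on held-out models and a clinical cohort:

```r
library(chemosig)

spec  <- simulationSpec(seed = 3)          # 40-patient PDC/PDX pool, etc.
study <- simulateStudy(spec, growthDrugs = "irinotecan")
ex    <- study$expression

pdcAucs <- panelAucs(study$response$panels$pdc$irinotecan)
valAucs <- panelAucs(study$response$panels$validation$irinotecan)

sig <- deriveSignature(
  normalizeLog2(ex$pdc), normalizeLog2(ex$pdx),
  pdcAucs, NULL,
  normalizeLog2(ex$validation), valAucs,
  config = runConfig(seed = 3), drug = "irinotecan")
sig
#> DrugSignature 'irinotecan': 26 genes
#>   top |weight|: g0411, g1969, g1511, g0984, g0085
length(intersect(geneIds(sig), study$truth$supports$irinotecan))
#> [1] 25
```

The derived 26-gene signature contains all 25 genes of the planted
irinotecan program. Projection onto the held-out PDC cohort anticorrelates
with measured viability AUC (higher score = more sensitive = lower AUC):

```r
testAucs <- panelAucs(study$response$panels$test$irinotecan)
proj <- projectSignature(sig, normalizeLog2(ex$test))
validateProjection(proj, testAucs)[c("rho", "p")]
#> $rho
#> [1] -0.6809789
#> $p
#> [1] 5.36127e-05
```

On the simulated 170-patient clinical cohort, the signature stratifies
overall survival in the mFFX arm (where the generator plants the effect)
and not in the gemcitabine arm:

```r
clin   <- study$clinical$clinical
scores <- sampleScores(projectSignature(
  sig, normalizeLog2(study$clinical$expression)))[clin$id]
mffx <- clin$arm == "mFFX"
st <- bestCutpoint(scores[mffx], clin$os_time[mffx], clin$os_event[mffx])
c(p = st$p, adjustedP = st$adjustedP, hr = st$hr)
#>            p    adjustedP           hr
#> 1.376589e-05 5.965243e-04 2.788923e-01

lab <- scores > st$cutpoint                 # fixed labels, control arm
logrankTest(clin$os_time[!mffx], clin$os_event[!mffx], lab[!mffx])$p
#> [1] 0.9125329
```

Signature-positive mFFX patients have a hazard ratio of 0.28 (log-rank
p ≈ 1e-5 at the selected cutpoint; p ≈ 6e-4 after correction for the
cutpoint scan), while the same labels show no association in the
gemcitabine arm — the arm-exclusivity pattern the design is meant to
detect.

A command-line interface over the same functions is installed at
`inst/scripts/chemosig` (subcommands `simulate`, `derive`, `project`,
`stratify`, `combine`, `report`).

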