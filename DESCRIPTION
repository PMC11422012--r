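Package: chemosig
Title: Drug-Specific Chemosensitivity Signatures from Patient-Derived Tumor Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation, projection and clinical validation of drug-specific
    transcriptomic chemosensitivity signatures from patient-derived tumor
    models. Implements TMM/log2 normalization of count matrices, dose-response
    viability AUC and xenograft growth-curve resistance (POR) scoring,
    ICA-based expression deconvolution with cross-model component matching,
    standard-deviation-interval feature-count optimization, Moore-Penrose
    pseudoinverse signature projection, maximally selected survival cutpoints,
    Cox and IPTW-adjusted Kaplan-Meier analysis of combination-therapy
    response, and a synthetic-data generator with planted response programs
    for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1), methods, SummarizedExperiment
Imports: stats, utils, tools, edgeR, survival, MASS, minpack.lm,
    jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
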