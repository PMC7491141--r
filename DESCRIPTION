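Package: methmediate
Title: DNA Methylation Mediation of Exposure Effects on Disease Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain linking a substance-use exposure to a clinical
    severity outcome through DNA-methylation mediators in blood: cohort
    outcome models (linear severity association, Cox proportional hazards,
    Kaplan-Meier trend test), dual epigenome-wide association scans with
    genomic-inflation diagnostics and dual-threshold candidate selection,
    single-site and joint causal mediation analysis with bootstrap inference
    and rho-sensitivity analysis under violation of sequential ignorability,
    and a validating two-step epigenetic Mendelian randomization with
    inverse-variance-weighted estimation, cis-meQTL instrument selection and
    LD pruning. Includes a synthetic-cohort generator with known ground truth
    for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
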