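Package: prmverify
Title: Verification of Targeted Proteomics Biomarkers from Parallel Reaction
    Monitoring Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control and biomarker-verification statistics for
    liquid-chromatography parallel reaction monitoring (LC-PRM) experiments
    with stable-isotope-labeled internal standards. Implements spectral
    contrast angle quality control of fragment-ion chromatogram areas with
    interference substitution and background imputation, blood-contamination
    filtering from spike-in dilution series, light/heavy peptide ratio
    quantification with full-process duplicate averaging, and nonparametric
    group comparison statistics (Mann-Whitney U, Benjamini-Hochberg FDR,
    ROC/AUC, sensitivity at fixed specificity). Includes a synthetic cohort
    generator that emulates a tumor/control uterine-aspirate PRM study for
    end-to-end testing without raw data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
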