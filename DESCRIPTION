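Package: DeltaRadiomics
Title: Delta-Radiomics Analysis of Longitudinal MR-Guided Radiotherapy Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for quantifying tumor image change over a
    course of MR-guided radiotherapy. Longitudinal 0.35T MR volumes are
    normalized to the median kidney signal, 73 standardized histogram and
    texture radiomic features (GLCM, GLRLM, GLSZM, NGTDM families) are
    extracted from the gross tumor volume at 64 intensity bins, and
    first-to-last-fraction feature ratios are screened against
    progression-free survival by univariate Cox regression with Holm
    correction and a maximally selected log-rank risk split. Feature
    spatial robustness is assessed by per-slice ROI erosion/dilation and
    Lin's concordance correlation coefficient. A synthetic cohort
    generator with known ground truth makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    RNifti,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, FeatureExtraction, Survival
RoxygenNote: 7.3.3
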