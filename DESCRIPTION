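Package: iccradiomics
Title: Clinical-Radiomic Modelling of Tumor Grading and Microvascular
    Invasion in Intrahepatic Cholangiocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for CT-based clinical-radiomic analysis of
    intrahepatic cholangiocarcinoma (ICC). Builds tumor and 5 mm peritumoral
    margin volumes of interest on portal-phase CT volumes, extracts the 45
    retained radiomic indices (grey-level descriptors, first-order, shape,
    GLCM, GLRLM, NGLDM and GLZLM families), assembles multicenter cohort
    tables with a missing-data policy, chained-equation imputation and
    correlation-based feature pruning, fits penalized and subset-selected
    logistic models of tumor grading (G3 versus G1-2) and microvascular
    invasion with a random-intercept center model and its variance partition
    coefficient, and validates models by stratified 50-fold cross-validation
    with paired one-sided permutation tests between nested model families.
    A synthetic phantom and cohort generator reproduces the statistical
    structure the analysis assumes, so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    RNifti,
    glmnet,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
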