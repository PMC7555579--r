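Package: wbdwi
Title: Automated Whole-Body Diffusion MRI Tumor Load Analysis for
    Lymphoma Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automatic analysis of longitudinal whole-body
    diffusion-weighted MRI (WB-DWI) for predicting and assessing
    chemotherapy response in Hodgkin's lymphoma. Computes apparent
    diffusion coefficient (ADC) maps from two-b-value acquisitions,
    segments hyperintense tissue on the high-b-value image with unedited
    percentage thresholds, extracts diffusion volume and first-order ADC
    histogram features at six thresholds, forms inter-timepoint
    percentage changes, and discriminates complete from partial
    responders with Mann-Whitney/ROC analysis. Includes a synthetic
    whole-body phantom generator with Rician noise and longitudinal
    response scenarios for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
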