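Package: dwidx
Title: Diagnostic Classification of Breast Lesions on Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating benign from malignant breast lesions on
    diffusion-weighted MRI (DWI). Implements a three-level qualitative
    morphological confidence score built from a malignancy-risk lexicon of
    DWI descriptors, quantitative apparent diffusion coefficient (ADC)
    analysis with Youden-index cutoff selection, rule-based combination of
    the two readings (and the analogous BI-RADS + ADC combination for
    dynamic contrast-enhanced MRI), and the diagnostic-performance
    machinery used to compare them: confusion-matrix metrics, univariate
    odds ratios with Woolf confidence intervals, empirical ROC curves with
    Hanley-McNeil standard errors, and independent (Hanley-McNeil) and
    paired (DeLong) AUC comparison tests. A synthetic-cohort generator
    emulates the class-conditional structure of a reference breast-lesion
    cohort so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    readxl,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
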