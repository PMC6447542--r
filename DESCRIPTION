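Package: preinjury
Title: Mining Pre-Injury Health Status from Matched Administrative Claims
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Phenome-wide screening of pre-injury health status in 1:1 matched
    case-reference cohorts built from visit-level administrative claims.
    Diagnosis codes are collapsed to three-character ICD-10 blocks and
    binarized over a five-year lookback window that excludes a peri-index
    event window detected from the visit-date histogram. Per-code matched
    McNemar tests with Benjamini-Yekutieli false-discovery-rate control and
    split-sample validation screen for over-represented codes; validated
    codes are reduced to factors by principal-component extraction with
    multi-criteria retention and a 0.2 loading cutoff; binary factor-based
    scores yield matched odds ratios with Wald confidence intervals on a
    held-out testing split. A synthetic claims generator with planted latent
    comorbidity factors and known odds ratios makes every stage testable
    without access to restricted registry data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse
Config/testthat/edition: 3
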