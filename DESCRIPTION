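Package: cbfcore
Title: Absolute Cerebral Blood Flow Thresholds for Ischemic Core from
    Serial CT Perfusion and PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives an absolute cerebral-blood-flow (CBF) threshold for
    infarction from co-registered serial CT-perfusion CBF maps and a PET
    neuronal-integrity image. Implements per-pixel temporal median CBF
    maps, PET uptake-defect segmentation against a contralateral reference
    region, grey/white-matter and vessel exclusion rules, class-balanced
    logistic regression of infarction on CBF, ROC analysis with
    optimal-operating-point extraction, and cohort aggregation. Includes a
    synthetic two-hemisphere phantom generator with known ground truth so
    the full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
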