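Package: onconer
Title: Pattern-Based Extraction of Tumor Entities from Chinese Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based named entity recognition for unstructured Chinese
    diagnostic-imaging text. Extracts primary tumor sites by malignancy-keyword
    sentence filtering, anatomy-dictionary matching and site refinement; primary
    tumor sizes by a measurement-expression grammar restricted to sentences
    related to the primary site; and metastatic tumor sites by metastasis-keyword
    co-occurrence, descriptor stripping and coordination-ellipsis completion.
    Includes entity-level micro precision/recall/F1 scoring with task-weighted
    aggregation, a subsampling robustness experiment, and a synthetic report
    generator with gold annotations so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
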