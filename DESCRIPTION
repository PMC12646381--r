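Package: ehrseq
Title: Autoregressive Next-Event Modelling of Longitudinal Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats a patient's electronic health record as a sentence in a
    small clinical language: OMOP-style relational tables are linearized into
    token sequences (demographics, relative time tokens, visit types,
    diagnosis/procedure/medication codes and decile-discretized lab values),
    a compact decoder-only transformer is trained with the next-token
    objective, and the fitted model is evaluated by visit-level greedy
    forecasting (precision/recall) and by a zero-shot censored-window
    diagnostic protocol reporting TP/FP/TN/FN at top-N candidate sets.
    Includes a synthetic longitudinal cohort generator with injected
    precursor-to-target conditional rules so every stage is testable without
    access to protected health information, a frozen-backbone linear-probe
    comparator, and attention-based token attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
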