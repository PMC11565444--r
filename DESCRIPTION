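Package: pathstruct
Title: Standardisation of Free-Text Pathology Reports with Confidence
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-stage extract-and-validate pipeline that turns free-text
    colorectal pathology reports into structured reports conforming to the
    Royal College of Pathologists (RCPath) colorectal dataset. An Extractor
    agent samples repeated model replies per query field and aggregates them
    by majority vote; a Validator agent judges and optionally corrects the
    extracted value. A five-term confidence score combines reply consistency
    from both agents and is rescaled per field by Platt calibration.
    Includes the full evaluation battery (accuracy, Cohen's kappa, AUROC of
    confidence against correctness, abstention curves), survival utilities
    (Kaplan-Meier, log-rank, Harrell's concordance index, an ordinal linear
    risk score), and a synthetic report generator plus a fully seeded
    simulated model backend so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
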