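Package: ntriss
Title: TRISS and NTRISS-Like Trauma Survival Probability Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Scoring, derivation and evaluation machinery for the TRISS family
    of trauma survival-probability models, including adjusted TRISS and three
    variants that replace the Revised Trauma Score with Best Motor Response,
    systolic blood pressure and a banded peripheral oxygen saturation, and the
    Injury Severity Score with the New Injury Severity Score. Provides registry
    reading with eligibility filtering and missing-physiology policies, ISS/NISS
    and RTS coding, packaged published coefficient sets per trauma mechanism,
    site-weighted logistic-regression coefficient derivation, ROC-based
    discrimination analysis with DeLong and bootstrap confidence intervals, and
    a calibrated synthetic trauma-registry generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
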