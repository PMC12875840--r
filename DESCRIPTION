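Package: slnbcea
Title: Cost-Utility Model of Sentinel-Node-Guided Versus Elective Neck
    Dissection in Early Oral Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing three neck
    management strategies for early (cT1T2N0) oral squamous cell carcinoma
    from the perspective of India's national insurance scheme: sentinel
    lymph node biopsy (SLNB) guided neck dissection, elective neck
    dissection (END) alone, and END with intraoperative frozen section.
    Provides the published parameter table as a validated fixture, a
    six-state annual-cycle cohort engine with half-cycle correction and
    age-dependent background mortality, cost/QALY/ICUR/INMB outcome
    aggregation, one-way deterministic and probabilistic sensitivity
    analyses (tornado, cost-effectiveness plane, acceptability curves),
    occult-metastasis threshold analysis, and an independent individual
    level microsimulation used as a validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
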