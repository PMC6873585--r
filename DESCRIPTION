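Package: adjtrast
Title: Cost-Utility and Budget Impact Model of Adjuvant Trastuzumab for
    HER2-Positive Early Breast Cancer
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Markov cohort state-transition model comparing one year of
    adjuvant trastuzumab added to standard chemotherapy against chemotherapy
    alone for HER2-positive early-stage breast cancer in the Philippine
    setting. Implements the five-state (disease-free survival, congestive
    heart failure, local recurrence, distant metastasis, death) annual-cycle
    cohort model with first-year cost tunnels, discounted cost / life-year /
    QALY accounting under healthcare-system and societal perspectives,
    incremental cost-effectiveness ratios and net monetary benefit,
    probabilistic sensitivity analysis with cost-effectiveness plane and
    acceptability curves, one-way (tornado) and two-way deterministic
    sensitivity analyses, threshold-price search for the trastuzumab
    treatment course, and a five-year national budget impact projection.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
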