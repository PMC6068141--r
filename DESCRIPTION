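Package: phifba
Title: pH-Dependent Constraint-Based Modeling of Cell Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs six-point enzymatic pH-activity profiles from
    tabular activity records, imputes missing critical points by homolog
    transfer and linear regression, injects the profiles as pH-specific
    flux-bound constraints into constraint-based metabolic models, and
    simulates proliferation, exchange fluxes and the OCR/ECAR
    (anti-Warburg) ratio across an intracellular-pH sweep.  Includes a
    gene- and reaction-level in-silico knockout screen ranked by
    selectivity and pH-specificity scores, a divide-and-conquer modulator
    search, robustness analyses, synthetic toy-cell fixtures, and the
    SNARF-1 ratiometric pH calibration utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
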