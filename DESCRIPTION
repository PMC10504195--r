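Package: bpcentile
Title: Pediatric Blood Pressure Reference Centiles by the LMS Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Constructs sex-stratified blood-pressure reference tables for
    young children from triplicate auscultatory measurements. Implements the
    triplicate measurement-selection rule (average of two consecutive readings
    differing by less than 5 mmHg), height Z-scoring against a pluggable LMS
    growth standard, a staged exclusion cascade with flowchart accounting,
    penalized-likelihood LMS (Box-Cox-Cole-Green) centile estimation with
    BIC selection over equivalent degrees of freedom, a quartic-polynomial
    comparison model, height-percentile by BP-percentile reference tables,
    fit diagnostics, and a calibrated synthetic-cohort generator for testing
    the full pipeline without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
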