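Package: btcpep
Title: Serum MALDI-TOF Peptidome Biomarker Discovery for Biliary Tract Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for serum peptidome profiling studies of
    biliary tract cancer (BTC): simulation of study cohorts with log-normal
    peak areas moment-matched to published group means, preprocessing of raw
    MALDI-TOF spectra (baseline subtraction, smoothing, total-ion-current
    normalization, peak detection and cross-spectrum alignment) into
    replicate-aggregated peak tables, Anderson-Darling-gated differential
    testing with Benjamini-Hochberg correction and ROC diagnostics, an
    exhaustive ratio/power threshold-classifier search with cross-validation,
    and peptide average/monoisotopic mass and charge-state utilities for
    verifying peak identities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    nortest,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
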