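Package: lfaquant
Title: Lateral-Flow Strip Densitometry, Logistic Calibration and
    Diagnostic Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies test- and control-line signals on lateral-flow
    immunoassay strip images via a smoothing, grayscale conversion,
    row-median profile collapse and prominence-thresholded local-minima
    pipeline; converts test/control signal ratios to analyte
    concentration through four-parameter logistic calibration curves
    fitted per strip batch; and evaluates diagnostic performance of the
    resulting concentration calls (median bias, correlation,
    sensitivity/specificity at clinical cut-offs, ROC). Ships a seeded
    synthetic strip-image generator with known ground truth so the whole
    pipeline can be exercised end to end without photographs, plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
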