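Package: mavescore
Title: Functional Scoring and Clinical Calibration of Variant Effect Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for multiplexed assays of variant effect (MAVEs) built on
    tiled duplex sequencing of selection experiments. Simulates saturation
    mutagenesis libraries, en-masse selection and paired-end tile sequencing;
    calls variants with a duplex posterior rule; converts count tables into
    enrichment ratios and rescaled functional impact scores with regularized
    errors; combines isoform maps; calibrates scores into log likelihood
    ratios of pathogenicity and ACMG/AMP evidence strengths via a Bayesian
    points framework; and evaluates map performance with ROC, balanced
    precision-recall and allele-frequency analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    pROC
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
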