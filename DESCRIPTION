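Package: cwqsar
Title: Correlation-Weight QSAR Models from SMILES Attributes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    models in which the single molecular descriptor is a sum of correlation
    weights attached to SMILES attributes (single SMILES atoms and adjacent
    pairs).  Weights are optimized by a Monte Carlo procedure under target
    functions that combine active/passive training-set correlations with the
    index of ideality of correlation (IIC) and the correlation intensity
    index (CII) evaluated on a calibration set.  Includes a Las Vegas style
    search over random four-way data splits (active training, passive
    training, calibration, validation), an applicability domain based on
    statistical defects of SMILES attributes, promoter extraction for
    mechanistic interpretation, a synthetic SMILES-like data generator for
    offline benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
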