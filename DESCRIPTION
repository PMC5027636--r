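Package: peasta
Title: Analysis of Paired Single-Cell Protein and RNA qPCR (PEA/STA) Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for combined proximity extension assay (PEA) protein and
    specific target amplification (STA) RNA quantification in single cells by
    microfluidic qPCR. Implements Ct-to-deltaCt normalization against
    zero-cell and lysis-buffer backgrounds, probabilistic detection calls and
    limits of detection, penalized contiguous linear-range selection on
    dilution standard curves with probe reliability classification, paired
    RNA-protein Spearman correlation statistics with permutation-null tests,
    in-silico gating differential detection screens with false-discovery-rate
    control, permutation-calibrated correlation network growth, standardized
    principal component analysis with random-forest time-point classification,
    quadrant-gated detection trajectory clustering, and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    pROC,
    nortest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
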