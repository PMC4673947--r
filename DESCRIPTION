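Package: cytoIR
Title: Dose Prediction from FTIR Spectra of Drug-Exposed Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for infrared-spectroscopy-based cytotoxicity bioassays.
    Simulates dose-structured cell FTIR absorbance spectra with
    drug-induced vibrational band shifts, performs asymmetric-least-squares
    baseline correction and 0-1 normalization, computes Biochemical Index
    Spectra (exposed-minus-control difference spectra), fits univariate
    partial least squares regression by NIPALS with cross-validated
    latent-variable selection, evaluates dose prediction over spectral
    windows with stratified train/test splits, and estimates LC50 from
    clonogenic mortality data with a two-parameter Hill model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
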