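Package: pkadyn
Title: Quantification of PKA Biosensor Imaging Responses to Optogenetic
    Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for fluorescence time series from protein
    kinase A (PKA) activity biosensors imaged during optogenetic stimulation
    of noradrenergic axons, in brain slices (two-channel FRET reporters such
    as AKAR3EV) and in vivo (single-chromophore reporters such as GAkdYmut).
    Provides ratiometric and single-channel trace normalization (dR/R0,
    dF/F0), photobleaching correction, stimulus-aligned epoching, per-ROI
    nonparametric responsiveness testing with threshold concordance,
    exponential onset and decay kinetics fitting, pharmacological
    normalization of repeated-stimulation designs, and a ground-truthed
    synthetic trace generator so that every stage of the pipeline can be
    validated against known parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
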