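Package: oxiNIR
Title: NIR Chemometrics for Lipid Oxidation Monitoring via Stepwise
    Decorrelation Variable Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate calibration of lipid-oxidation markers (free
    acidity, K232, K270, delta-K, peroxide value, anisidine value and the
    TOTOX index) from near-infrared absorbance spectra. Implements the
    SELECT stepwise selection-decorrelation algorithm for wavelength
    selection, ordinary least squares regression on the selected channels
    with column autoscaling, leave-one-out cross-validation and PRESS
    statistics for model-size choice, and a synthetic deep-frying study
    generator with marker-linked absorption bands so the whole pipeline
    can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
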