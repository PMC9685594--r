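Package: faimscv
Title: Predicting Optimal FAIMS Compensation Voltages for Peptide Ions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling peptide transmission through a FAIMS
    (high-field asymmetric waveform ion mobility spectrometry) device as a
    function of the compensation voltage (CV). Computes a 76-parameter
    physicochemical/QSAR feature vector from peptide sequence and charge,
    summarises CV-resolved intensity profiles (weighted-average CV, span,
    top-bin fraction), trains Lasso and stacked-ensemble regressors for the
    CV of maximum transmission, and implements a two-stage pilot/refine
    workflow that turns low-precision predictions into high-precision CV
    assignments for parallel-reaction-monitoring (PRM) inclusion lists. A
    synthetic benchmark generator with bell-shaped transmission profiles and
    detection censoring makes the full pipeline testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
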