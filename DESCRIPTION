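Package: nirbean
Title: NIRS Calibration Workflow for Bean Flour Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Near-infrared reflectance spectroscopy (NIRS) calibration
    toolkit for predicting compositional traits (protein, starch, dietary
    fiber, phytate, minerals, seed colour and more) of rice bean and adzuki
    bean flours from log(1/R) spectra. Implements scatter corrections
    (SNV, detrend, SNV-DT, MSC, WMSC), gap-segment derivative math
    treatments in the "derivative, gap, smooth1, smooth2" convention,
    modified partial least squares (mPLS) regression with cross-validated
    factor selection and iterative outlier elimination, the standard
    calibration/validation statistics (SEC, SECV, SEP, SEP(C), bias, RSQ,
    RPD, paired t-test), an exhaustive math-treatment grid search, and a
    synthetic flour-spectra generator with known ground truth for
    benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
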