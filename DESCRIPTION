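Package: nirsbp
Title: Continuous Blood-Pressure Estimation from NIRS-PPG Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for noninvasive continuous mean-arterial-pressure
    estimation from forehead near-infrared spectroscopy photoplethysmography
    (NIRS-PPG) recordings: ambient-light correction, accelerometer-based motion
    artifact masking, Daubechies wavelet band-pass filtering, optical-density
    conversion and interquartile-range normalization, beat segmentation with
    percentile-based pulse quality control and four-beat ensemble averaging,
    four-Gaussian decomposition of the pulse first derivative with fiducial-peak
    labeling (P1, P2, dicrotic notch and peak), amplitude-independent feature
    extraction (P2/P1 ratio, heart rate, P1-P2 slope), and subject-specific
    calibration against reference arterial pressure by ordinary least squares
    and by Gaussian-process regression with per-feature length scales.
    Includes a seeded synthetic-recording generator with known morphology and
    pressure trajectories so that every stage has an exact recovery oracle, and
    agreement statistics (R-squared, RMSE, MAE, Bland-Altman limits, paired
    model comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
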