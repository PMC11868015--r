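Package: hrvrace
Title: Heart Rate Variability and Haemodynamics After an Exercise Stop
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for ultra-short-term heart rate
    variability (HRV) and haemodynamic indices measured at a brief stop during
    strenuous endurance exercise. Provides an integral pulse frequency
    modulation (IPFM) simulator for two-group exercise cohorts with
    configurable beat artifacts, median-filter artifact detection with
    deletion, linear, cubic-spline and ARIMA correction, time-domain (RMSSD,
    SDNN) and frequency-domain (VLF/LF/HF/TP) HRV via FFT on an evenly
    resampled tachogram, heart-rate reserve and recovery, pulse pressure and
    rate-pressure products, and a non-parametric group-comparison layer
    (median/IQR, Mann-Whitney U, chi-square, multivariable logistic
    regression) with walker detection from power or speed traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
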