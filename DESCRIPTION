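Package: radarvitals
Title: Vital-Sign Extraction from Laterally Positioned FMCW Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contactless breathing- and heart-rate monitoring from a
    frequency-modulated continuous-wave (FMCW) radar observing a sleeping
    subject. Implements range-bin selection driven by a temporal phase
    coherency statistic, autocorrelation-based breathing-rate estimation,
    interval-based heart-rate estimation from the normalized heart-band
    phase signal, and a stationary-wavelet (Symlet 4) ECG reference detector.
    Includes a seeded simulator of range-time radar signals for three radar
    placements around a bed (foot end, nightstand, ceiling) with matched
    belt and ECG reference channels, and agreement metrics (detection rates,
    tolerance proportions, MAPE) for comparing radar positions against a
    contact reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
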