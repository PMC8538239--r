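Package: pulsefuse
Title: Camera-Based Heart Rate by Fusing Remote Photoplethysmography and
    Ballistocardiography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates heart rate from facial video by combining the
    color-based pulse signal (remote photoplethysmography, extracted from
    skin-region RGB traces via pulse blood-volume projection and independent
    component analysis) with the motion-based pulse signal (remote
    ballistocardiography, extracted from tracked facial-point trajectories
    via principal component analysis). The two signals are fused by ensemble
    averaging, PCA, or ICA with spectral signal-to-noise selection, and heart
    rate is read off the dominant in-band frequency. Includes face-relative
    region-of-interest geometry with pyramidal Lucas-Kanade point tracking, a
    synthetic-data simulator with ground-truth heart rate for the three
    study conditions (normal, facial expressions, human-computer
    interaction), and Bland-Altman agreement metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
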