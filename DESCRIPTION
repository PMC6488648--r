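Package: reefpulse
Title: Coral Colour and Polyp Activity Time Series from Fixed Underwater
    Observatory Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Extracts behavioural and physiological time series of
    cold-water coral (Lophelia pertusa) from hourly image sequences
    recorded by a fixed underwater observatory, and analyses them jointly
    with environmental sensor records.  The imaging side computes a coral
    colour series (the CIELab a-channel averaged over a texture-segmented
    live-coral region) and a polyp activity series (the fraction of
    polyp-mask pixels classified as extended polyps by a patch-based
    convolutional network).  The analysis side maps irregular, gappy
    series onto common hourly grids by bracketed linear interpolation,
    computes daily averages and pairwise correlations, and provides a
    Morlet continuous wavelet transform with bias-corrected power,
    chi-squared and Monte Carlo red-noise significance testing, and
    wavelet coherence with phase.  A synthetic-scene generator renders
    reef-like image sequences and sensor signals with known ground truth
    so the whole pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    farver,
    png,
    class,
    EBImage,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
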