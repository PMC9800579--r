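Package: patchRoll
Title: Energetics and Kinetics of Annexin-Driven Membrane-Patch Rolling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for annexin-induced rolling of supported
    membrane patches with free edges. Implements a Helfrich spiral
    rolling-length model (rolled length versus adhesion energy and
    spontaneous curvature, with parameter sweeps and critical-factor
    detection), quantification of rolling and unrolling kinetics from
    time-lapse fluorescence image stacks (frame differencing, logistic
    fits for the rolling time constant, relative area increase,
    edge-localization line profiles, Welch's t comparisons), AFM
    height-map analysis (2D-FFT lattice period of close-packed trimer
    crystals, bimodal height-domain segmentation with area fractions),
    and Monge-gauge mean-curvature mapping of membrane midplanes fitted
    to lipid-particle coordinates. Ships synthetic-data generators that
    emulate each input modality with ground-truth records, so every
    analysis stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    mclust,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
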