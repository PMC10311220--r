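Package: neuroculture
Title: Quantitative Analysis of Neural Culture Electrophysiology and Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative characterization of dissociated (2D) and
    aggregated (3D) neural cultures: bandpass filtering and RMS-threshold spike
    detection on extracellular multi-electrode array recordings, ISI-rule burst
    detection with burstiness and interburst-interval metrics, two-channel
    fluorescence colocalization (Mander's overlap coefficients, Pearson
    correlation, threshold overlap score) with rolling-ball background
    subtraction, Sholl profiles and branch morphometrics of traced astrocyte
    arbors, and astrocyte density in distance zones around an aggregate. A
    synthetic-data generator produces inputs with exact ground truth for every
    stage, so the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    signal,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
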