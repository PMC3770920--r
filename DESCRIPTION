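Package: meaburst
Title: Burst, Superburst, and Calcium Transient Detection for Cultured
    Neuronal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detection and characterization of epileptiform activity in
    dissociated neuronal cultures recorded with microelectrode arrays (MEA)
    and calcium imaging.  Implements median-normalized amplitude thresholding
    for extracellular spike detection, network burst detection from the total
    spiking rate, a Gaussian-window indicator for seizure-like superbursts,
    and derivative-threshold detection of calcium pulses and long
    superoscillations, together with seeded synthetic-data generators that
    emulate control-like and hyaluronidase-like recordings so that every
    detector can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
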