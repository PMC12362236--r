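Package: flashros
Title: Radiolysis ROS Kinetics Under FLASH and Pencil-Beam-Scanning Dose Delivery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates water-radiolysis reactive-oxygen-species (ROS)
    chemistry driven by arbitrary time-varying dose-rate waveforms, with a
    mass-action reaction network solved as a stiff ODE system. Couples the
    chemistry to a proton pencil-beam-scanning (PBS) delivery model with a
    Gaussian spot kernel, equal-MU weighting and dwell/transition timing, so
    that ultra-high-dose-rate (FLASH) versus conventional sparing can be
    quantified through alkyl-hydroperoxide (ROOH) production, ROS-volume
    histograms and the standard PBS dose-rate metrics (ADR, DADR, PBSDR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
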