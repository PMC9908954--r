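Package: cssim
Title: Adaptive Campaniform-Sensillum Load Feedback in a Dynamically
    Scaled Insect Leg
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator of load sensing in a dynamically scaled
    stick-insect (Carausius morosus) middle leg. Implements the adaptive
    phenomenological model of campaniform sensillum (CS) discharge for the
    four major leg CS groups (3, 4, 6A, 6B), product-of-exponentials
    forward and inverse kinematics of the three-joint leg, dynamic-scaling
    arithmetic linking animal and robot step periods, a quasi-static
    synthetic strain generator standing in for the physical robot
    (hollow-square beam bending at two gauge rosette sites, amplifier,
    12-bit ADC, moving median filter), and declarative runners for the
    ramp-hold-release, directional-loading, loaded-stepping, transient-load
    and foot-slip protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
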