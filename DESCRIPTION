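Package: atquant
Title: Antithrombin Activity Quantification from Photon-Counting Absorbance Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies antithrombin (AT) activity from chromogenic anti-Xa
    assay photometry on a digital-microfluidic point-of-care device. Converts
    time-resolved photon-count traces to dark-corrected absorbance change
    rates via a double-pass (reflection-transmission) Beer-Lambert model,
    fits and inverts linear calibration curves, and computes the standard
    method-validation statistics (repeatability CV, two-sample
    Kolmogorov-Smirnov consistency, relative differences against a reference
    instrument). Includes a virtual instrument that forward-simulates the
    enzymatic reaction kinetics, optics, and photon-counting noise so the
    whole pipeline is testable against known ground truth without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
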