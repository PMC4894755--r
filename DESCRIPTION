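Package: turncycle
Title: Step-Cycle, Load-Response and Central Pattern Generator Rhythm
    Analysis for Turning Insect Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for body-side-specific motor output in a
    turning insect: segmentation of stance-anchored step cycles from tarsal
    contact signals, electromyogram conditioning (rectification, boxcar and
    Gaussian smoothing, per-step normalization, antagonist crosstalk
    subtraction), peristimulus time histograms and Michelson-contrast
    scoring and classification of responses to campaniform-sensilla load
    stimuli, circular statistics (mean resultant vectors, Rayleigh test,
    phase histograms) for phase coupling of motoneuron activity to the step
    cycle, and burst-based frequency analysis of slow pilocarpine-induced
    central pattern generator rhythms. A synthetic-data generator emulates
    step trains, phase-locked spike trains, load-stimulus trials and slow
    alternating rhythms with known ground truth so that every stage of the
    pipeline is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
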