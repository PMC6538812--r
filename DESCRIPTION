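Package: eqdose
Title: Equivalent-Dose Modeling of Chemotherapy Uptake and Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic pharmacokinetic/pharmacodynamic modeling of doxorubicin
    treatment response in cell culture. Simulates a three-compartment drug-uptake
    model (extracellular, free intracellular, nucleus-bound) under arbitrary
    piecewise treatment schedules, computes the equivalent dose (the peak
    nucleus-bound drug concentration) as a unified measure of delivered effect,
    and fits logistic cell-population models with time-dependent death rates.
    Inverse procedures estimate how sensitizing agents (efflux-pump inhibitors,
    DNA-repair inhibitors) modulate individual rate constants from
    population-scale cell-count data, via response-surface matching of treatment
    dynamics and monotonically constrained least squares. Includes the
    fluorescence image-processing pipeline (illumination correction, spectral
    linear unmixing, signal-to-concentration calibration) and synthetic-data
    generators with known ground truth for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    Matrix
Config/testthat/edition: 3
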