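Package: menmod
Title: Magnetoelectric Nanodisc Neuromodulation: Transduction, Membrane
    Summation and Fluorescence Trace Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models and analysis tools for magnetoelectric-nanodisc (MEND)
    neuromodulation experiments. Converts magnetic-field protocols and particle
    geometry into single-particle membrane potentials and dosimetry quantities;
    implements a repetitive subthreshold-depolarization membrane model with
    cable-theory spatial summation, calibrated to printed experimental anchors;
    provides the calcium-imaging (dF/F0) event-detection statistics and the
    fibre-photometry processing chain (zero-phase Butterworth filtering,
    double-exponential debleaching, isosbestic motion subtraction, trial
    segmentation and classification); and ships synthetic-data generators with
    ground truth so every analysis stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
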