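Package: nucleomech
Title: Quantitative Image Analysis of Nuclear Mechanics Assays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bespoke quantification pipelines for live- and fixed-cell
    mechanobiology imaging: particle-tracking microrheology (bead
    detection, proximity-principle linking, time-averaged mean squared
    displacement and diffusivity fits), ratiometric spectral FRET
    readout of a nuclear-envelope tension sensor (inverted FRET index,
    donor/acceptor peak ratio), fluorescence-lifetime (FLIM) chromatin
    compaction readout by truncated-exponential maximum likelihood,
    nuclear-envelope morphometry (excess of perimeter over the convex
    envelope), front-rear nuclear polarity density maps with
    Kolmogorov-Smirnov and Cramer-von Mises tests, scalar per-cell
    quantifications (nuclear/cytoplasmic ratio, dots per area, focal
    adhesion counts, actin structure-tensor coherency, spreading
    ratio), and 2D cell motility metrics. A synthetic-data generator
    produces every input modality with known ground truth so each
    stage is verifiable offline by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
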