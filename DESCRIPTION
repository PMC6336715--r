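Package: axdefine
Title: Artifact Removal and Quantification of Fluorescently Labeled Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Removes autofluorescence and other fluorescent artifacts from
    multi-channel z-stack fluorescence microscopy images of labeled axonal
    fibers, and semi-automatically quantifies axon density in the cleaned
    images. Implements the DEFiNE-style three-stage cleaning procedure
    (size/circularity-based large particle removal on z-slices, digital
    subtraction of a dedicated autofluorescence channel, and small particle
    removal on the maximum intensity projection), background-region
    calibrated fiber quantification, a non-interactive settings
    recommendation step, and a synthetic phantom generator with ground-truth
    masks for validation. Batch processing is exposed both as R functions
    and as a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    optparse,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
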