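Package: HiCstripes
Title: Architectural Stripe Detection and Benchmarking for Chromosome
    Conformation Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects architectural stripes in Hi-C and Micro-C contact maps.
    Candidate stripes are seeded at persistent local maxima of a marginal
    pseudo-distribution computed over a diagonal band of the contact matrix,
    extended into two-dimensional rectangles by geometric estimation of their
    horizontal (width) and vertical (height) domains, and scored by the
    relative change of the signal inside the stripe against its flanking
    neighbourhood. Includes a benchmarking layer with per-bin classification
    and stripe-level recognition metrics against ground-truth extrusion
    barriers, a synthetic planted-stripe contact-map generator for controlled
    evaluation, readers for cooler-format and plain-text contact matrices,
    an HDF5 results archive, BEDPE export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    rhdf5,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
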