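Package: spheroidfab
Title: Selection, Photo-Crosslinking and Size-Gated Sorting Pipeline for
    Gelatine-Encapsulated Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A testable software twin of an automated platform that produces
    uniform gelatine-encapsulated tumour spheroids (GESs). The package
    segments spheroids and debris from paired darkfield/fluorescence chamber
    images, computes per-object morphometry (equivalent-circle diameter and
    4*pi*A/P^2 circularity), runs a viability gate followed by a four-stage
    selection-filter cascade (size/area/morphology, proximity, overlap,
    boundary), renders photomasks for selective 405 nm photo-crosslinking,
    and simulates the downstream size-gated microfluidic sorter, the
    fluorescence spike detector, and single-GES dispensing into a 96-well
    plate. A seeded synthetic image and population generator with exact
    ground truth stands in for the optical hardware, and a four-parameter
    logistic module fits dose-response curves and IC50 fold changes for
    GES-based drug screens.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
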