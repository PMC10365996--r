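Package: secretomap
Title: Spatiotemporal Single-Cell Secretion Mapping from Plasmonic
    Microwell Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Label-free analysis of single-cell protein secretion from
    time-lapse transmission-intensity images of plasmonic (nanohole-array)
    microwell arrays. Segments the cell in every frame with a multi-scale
    filter bank and a random-forest pixel classifier, converts paired
    sensing/reference wells into drift-corrected 4D spatiotemporal
    secretion maps, reduces the maps to total-intensity-change (TIC) and
    secretion-area curves, detects secretion onset and plateaus, fits
    linear kinetic segments, classifies secretion profiles (types I, II,
    III), and summarizes populations. Includes a ground-truthed synthetic
    scene simulator of the optical transduction (resonance redshift of an
    extraordinary-optical-transmission line probed by a narrowband LED) so
    every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    randomForest,
    stats,
    graphics,
    grDevices,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
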