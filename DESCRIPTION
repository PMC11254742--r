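Package: puckcall
Title: Bead Barcode Calling from Multi-Round Epifluorescence Puck Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-processing pipeline that turns repeated tiled
    epifluorescence acquisitions of a Slide-seq bead array ("puck") into a
    per-bead spatial map of DNA barcodes. Each of 14 sequencing rounds images
    the puck as overlapping brightfield and four-channel fluorescence tiles;
    the pipeline segments beads, stitches tile masks into a mosaic, rigidly
    registers every round to the first, corrects residual local distortion
    patch by patch, links each bead across rounds under a strict congruence
    rule, and calls the per-round base from the four fluorescence gray values
    with a small network robust to channel crosstalk. A synthetic-acquisition
    generator with full ground truth (bead positions, per-round motion,
    washout, crosstalk, noise) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
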