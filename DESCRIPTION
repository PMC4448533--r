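Package: bettiscreen
Title: Homology-Based Region-of-Interest Screening for H&E Histology Tiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens low-magnification hematoxylin-and-eosin (H&E) tile
    images of colonic tissue for regions of interest using cubical homology.
    Each tile is binarized with an automatic per-image threshold, decomposed
    into a segment grid, and the 1-dimensional Betti number (the number of
    enclosed windows in the stained-tissue mask) of every segment is computed,
    normalized by the segment's non-blank tissue fraction, and compared
    against a flagging threshold. Includes a seeded synthetic-tissue
    generator emulating normal mucosa, adenocarcinoma, inflammation and
    slide-artifact phenotypes, overlay rendering of segment scores, and
    contingency-table evaluation against reference labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
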