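Package: pulpscan
Title: Cavity-Based Quantification of Internal Compression Damage in Citrus CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies internal mechanical damage in mandarin fruit from
    grayscale CT section images. Implements a mask-and-region-growing
    segmentation pipeline that isolates the dark central pulp cavity
    (binarization, erosion-based masking, image multiplication, background
    conversion, morphological refinement, seeded region growing), measures its
    pixel area before and after compression, and derives the cavity-based
    damage rate A = (S2 - S1)/S1 x 100. Companion tools compute postharvest
    storage-quality metrics (respiration rate, decay rate, percent change
    versus control) and fit linear models linking compression deformation to
    damage and storage decay rates. A synthetic phantom generator with exact
    pixel-level ground truth stands in for CT scans so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
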