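Package: veinTC
Title: Quantification of Wall-Ingrowth Deposition in Phloem Parenchyma
    Transfer Cells of Leaf Minor Veins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying polarized wall-ingrowth deposition in
    phloem parenchyma transfer cells (PP TCs) from multi-channel confocal
    cross-sections of leaf minor veins. Builds cell-adjacency graphs from
    integer label maps, extracts cell/cell interfaces with physical lengths,
    measures wall-thickness profiles and ingrowth coverage fractions, assigns
    the five-class deposition grade and ordinal ingrowth scores, classifies
    abaxial/middle/adaxial cell positions, and implements two calibrated
    fluorescence statistics: the internal-standard relative intensity F
    (marker fluorescence calibrated against a general wall stain, cancelling
    depth attenuation) and the membrane-enrichment factor FC (marker
    fluorescence per unit wall length). A seeded synthetic vein generator
    renders ground-truth cross-sections so every stage is testable without
    real microscopy data; cohort-level survey statistics and Student's t
    comparisons are provided for multi-vein studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    EBImage,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Visualization
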