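Package: perfusim
Title: Transport Design and Image Quantification for Microfluidic Perfusion Stem-Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for perfused microfluidic cell-culture
    chambers in which continuous medium flow washes out cell-secreted
    (autocrine/paracrine) ligands. Provides a closed-form design calculator
    converting chamber geometry, flow rate, ligand diffusivity and receptor
    kinetics into Peclet and Damkohler numbers, wall shear stress and a
    transport-regime classification; a two-dimensional steady
    advection-diffusion-reaction solver for a ligand secreted and recaptured
    on the cell-covered chamber floor, with capture/washout mass bookkeeping;
    a synthetic phase-contrast and fluorescence image generator for adherent
    colonies with exact ground-truth masks; and the measurement pipeline it
    feeds: bright-feature colony segmentation, cell-area fold-increase growth
    curves, reporter-positive area fractions, condition aggregation with a
    pooled-variance t-test, and qPCR standard-curve relative expression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    EBImage,
    stats,
    utils,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
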