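Package: dyadomics
Title: Multi-Block Chemometric Analysis of Longitudinal Mother-Infant
    Dyad Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Chemometric pipeline for longitudinal mother-infant dyad
    studies integrating fecal metabolome and 16S microbiota tables.
    Implements PLS-DA validated by repeated double cross-validation with
    rank-product marker selection and permutation tests on NMC, AUROC and
    discriminant Q2; ComDim (CCSWA) common-component analysis and
    multi-block PLS-DA on Frobenius-scaled concatenated blocks;
    thresholded Pearson correlation networks and PLS trend analysis of
    milk composition against lactation day. Ships a seeded synthetic
    dyad-data generator reproducing the breastfeeding-to-weaning design
    (five consecutive-day blocks, BM/FBM/W diet periods, compositional
    OTU tables) with ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
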