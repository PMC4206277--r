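Package: decoymap
Title: Residue-Residue Contact Prediction from Decoy Ensembles and
    Evolutionary Couplings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies native residue-residue contacts inside low-energy
    ab initio structure-prediction decoys. Each candidate contact is encoded
    through labelled contact graphs of its structural neighbourhood
    (topological, spectral, physicochemical and evolutionary descriptors,
    238 inputs), classified by an undersampled ensemble of five
    Gaussian-kernel support vector machines with percentile-bin probability
    calibration, and the ensemble probability is combined with the contact's
    occurrence frequency across the decoy ensemble and with external
    evolutionary coupling scores. Emits ranked contact lists in the CASP RR
    dialect and bounded-Lorentz distance restraints for folding engines, and
    evaluates predictions with accuracy/coverage at top L/10, L/5 and L/2,
    stratified by sequence-separation range and alignment depth. A seeded
    synthetic generator of native structures, decoy ensembles, alignments
    and coupling score files supports fully self-contained training and
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    e1071,
    igraph,
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
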