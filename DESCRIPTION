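Package: ac4ctools
Title: Computational Analysis of tRNA Cytidine Acetylation Loss
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of the computational pipeline used to
    study loss of Thumpd1/NAT10-dependent N4-acetylcytidine (ac4C) in
    transfer RNA: calling acetylation sites from chemical-probing
    (ac4C-seq) misincorporation and reverse-transcription-stop signals,
    modification-tolerant tRNA isodecoder quantification and differential
    abundance, E/P/A-site codon occupancy from monosome and disome
    (ribosome-collision) footprints with meta-codon profiles and a
    translation-efficiency classifier, synonymous codon-usage and
    dipeptide bias statistics with a wobble-decoding table, and Mendelian
    segregation tests for genetic crosses. A synthetic-data module
    generates every pipeline input with known ground truth so each stage
    is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
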