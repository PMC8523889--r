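Package: fourdtv
Title: Transversion Distances at Fourfold-Degenerate Sites and
    Whole-Genome-Duplication Dating
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dating lineage-specific whole-genome duplications
    in cyprinid fishes from transversion distances at fourfold-degenerate
    third codon positions (4dTv). Computes raw and HKY-corrected 4dTv per
    paralogous gene pair, builds peak distributions and converts modal
    peaks to absolute ages against the teleost 3R calibration; also
    provides k-mer genome-size estimation, assembly summary statistics,
    homology-hit filtering with collinear-block anchor chaining,
    pseudogene lesion classification, and seeded simulators (HKY codon
    pairs with a duplication burst, k-mer depth spectra, lesioned gene
    copies, collinear anchor sets) so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
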