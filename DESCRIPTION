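Package: molbarval
Title: Mock-Community Validation of 16S Metabarcoding Assays for Molluscs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design and validate environmental-DNA (eDNA)
    metabarcoding assays against mock communities of known template copy
    number. Implements degenerate-primer in-silico PCR and amplicon
    extraction, competitive-PCR internal-standard copy-number estimation,
    mock-community recipes with assay-conditional expected read fractions,
    a paired-end amplicon read simulator with ground truth (two-step
    library construct, sequencing error, chimeras, PhiX decoys), read
    merging and primer/spacer trimming with per-stage accounting,
    exact-match taxonomic assignment, greedy 97% OTU clustering with
    local-alignment identification, and observed-versus-expected abundance
    statistics including blocking-primer efficacy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
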