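Package: discrimotif
Title: Discriminative Motif Discovery with Binding-Site Hidden Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers nucleotide sequence motifs whose occurrence frequency
    differs between conditions of one or more contrasts of sequence sets,
    e.g. ChIP-Seq or CLIP signal versus control. Provides heuristic seed
    finding over IUPAC regular expressions, discriminative training of
    binding-site hidden Markov models under several objective functions
    centered on the mutual information of condition and motif occurrence
    (MICO), likelihood-ratio significance filtering with motif-space
    correction, iterative discovery of non-redundant motif sets gated by
    conditional mutual information, and a synthetic benchmark with
    information-content-controlled motif implantation, recognizability
    reference models and nucleotide- and site-level evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
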