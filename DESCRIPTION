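Package: abcconftor
Title: Structural Classification and Conformational States of ABC Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for identifying transmembrane ABC
    transporter structures from Pfam/HMMER domain evidence, assigning them
    to structural families by TM-score structure alignment against a
    reference library, and classifying their conformational state
    (bottom-open versus bottom-closed) from the cross-NBD Walker-A to
    ABC-signature C-alpha distances ("conftor" measure). Includes rigid-body
    (Kabsch) superposition, a sequence-independent TM-score-maximising
    aligner with a compiled dynamic-programming core, HMMER3 per-domain
    output parsing and filtering, functional-unit calling, synthetic
    fixture generators with planted ground truth, and a batch
    classification pipeline with flat-file metadata output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
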