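Package: helentronscan
Title: Structural Annotation and Classification of Helentron and HINE
    Transposable Elements
Version: 0.3.0
Authors@R:
    person("Repeat", "Curation Lab", email = "repeats@example.org",
           role = c("aut", "cre"))
Description: Detection, classification and validation of Helentrons
    (endonuclease-encoding rolling-circle transposons) and their
    non-autonomous partners (HINEs, including Drosophila DINE-1-like
    elements). Provides a palindrome and inverted-repeat engine for
    subterminal inverted repeat (subTIR) and 3' stem-loop discovery,
    window-based structural annotation and typing (HINE, Helentron,
    canonical Helitron, proto-Helentron), family and subfamily
    classification from shared subTIRs and 3'-terminal identity,
    paralogous empty-site validation of element boundaries, target-site
    analysis (TT preference, variable T runs, absence of target-site
    duplication), Rep protein motif-2 diagnostics, and a synthetic-genome
    simulator with planted elements and full ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
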