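Package: mitescan
Title: Genome-Wide Discovery of Miniature Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of miniature inverted-repeat transposable
    elements (MITEs) in genome sequence databases. Candidate elements are
    detected from terminal inverted repeats (TIRs) and target site
    duplications (TSDs), validated by genome-wide full-length copy counting
    and flanking-sequence diversity, and reported as one exemplar per
    family. Redundant computation is avoided by progressively hard-masking
    the genome with a filter database of already-deposited families and by
    an optional sampling-theory early stop for the discovery phase. A
    synthetic-genome simulator with planted MITE families, identical-flank
    decoy repeats and simple-repeat stretches provides a fully reproducible
    test bed, together with an evaluator that scores recall and precision
    against the simulator's truth records.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
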