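Package: protlift
Title: Reconciliation of DNA- and Protein-Based Genome Annotation Lift-Over
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Merges two candidate annotations of a target genome -- one
    produced by DNA-alignment lift-over (Liftoff-style, with UTRs) and one by
    spliced protein-to-genome alignment (miniprot-style, CDS only) -- into a
    single annotation that maximizes protein identity to the reference.
    Implements CDS chaining over paired protein alignments, open reading
    frame repair for deleterious mutations, gap-compressed protein identity,
    gene-copy and processed-pseudogene filtering, mutation classification,
    and GFF3 input/output. Includes a synthetic fixture generator that plants
    the failure modes of both aligner families for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
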