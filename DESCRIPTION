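Package: quadedit
Title: Flipon-Aware Annotation of A-to-I RNA Editing Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates nonsynonymous A-to-I RNA editing sites with respect to
    flipon sequences: scans for G-quadruplex motifs on the strand of the
    edited adenosine within a configurable window, classifies edited exons by
    their position within transcript isoforms, computes overlaps of edited
    exons with Alu-family repeats, tests association of edited exons with
    alternative splicing via isoform-intron overlap, and detects quadruplex
    motifs that are completed by the A-to-G substitution introduced by
    editing. Ships a synthetic-data generator with planted, recorded truth so
    that every pipeline stage is testable without external genome resources,
    plus a permutation-based enrichment test of quadruplex-edit association.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
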