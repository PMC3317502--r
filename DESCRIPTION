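Package: igrec
Title: Discovery, Classification and Expression Calling for Ig-Like Receptor Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising immunoglobulin-like receptor (Ig-receptor)
    gene families such as the leukocyte Ig-like receptors (LILR), their rodent
    counterparts (PIR) and the related killer Ig-like receptors (KIR). The
    package finds candidate open reading frames on genomic contigs, detects
    Ig domains with position-specific scoring matrices, assigns domains and
    receptors to families by neighbour-joining phylogenetics with
    pairwise-deletion amino-acid p-distances and bootstrap support, adjudicates
    novelty against previously annotated sequences, classifies receptors as
    inhibitory, activating or soluble from transmembrane segments, ITIM motifs
    and transmembrane arginines, and calls expression from ungapped short-read
    coverage. A synthetic-fixture generator produces receptor genes with known
    family, architecture, signalling class and expression truth so that every
    stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
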