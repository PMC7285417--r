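Package: fullcirc
Title: Full-Length Circular RNA Sequence Extraction and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the full-length sequence of circular RNAs (circRNAs)
    from three inputs: the back-splice junction coordinates reported by any
    circRNA prediction tool, a reference genome in FASTA format, and a gene
    annotation in GTF or GFF3 format. For each predicted circRNA the package
    selects the best host transcript by interval containment followed by a
    deterministic tie-break cascade, classifies the circRNA as exonic,
    intronic, or other, and emits its full-length sequence by splicing the
    host transcript's exons within the circRNA boundary (or taking the raw
    genomic span for non-exonic calls). Includes a deterministic synthetic
    fixture generator (genome, annotation, calls, ground truth) so the whole
    workflow is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
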