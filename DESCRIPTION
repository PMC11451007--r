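Package: isocollapse
Title: Locus-Centric Collapse, Classification and Validation of Long-Read RNA-seq Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locus-centric analysis of per-sample long-read RNA-seq
    transcript models: disambiguation of a target gene from an overlapping
    readthrough (conjoined) gene, gene-level TPM quantification, open reading
    frame prediction on spliced transcripts with the longest-per-stop-codon
    rule, UTR decomposition, tolerance-based cross-sample transcript merging
    with compositional identifiers, prediction of nonsense-mediated decay by
    the 50-nt rule, novelty and category calls against a reference annotation,
    transcript and ORF usage statistics with tissue-specificity calls, and
    corroboration of transcript ends and splice junctions against TSS peak,
    polyA-site and junction atlases. Includes a fully specified synthetic
    two-gene locus generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
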