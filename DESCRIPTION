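Package: isoformAlign
Title: Genome-Anchored Three-Layer Alignment of Protein Isoforms
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pairwise comparison of protein isoforms of the same gene at
    three interlinked layers: shared and unique exonic regions at the
    transcript level (t-blocks), genome-overlapping codon pairs at the
    reading-frame level (c-blocks), and matched or altered protein regions
    (p-blocks). Every altered protein region is attributed to its upstream
    mechanism: alternative transcription start sites versus 5' UTR splicing
    at the N-terminus; simple and compound splice events, junction-split
    "ragged" codons, and frame-restoring "snapback" frameshifts internally;
    and splice-driven versus frameshift-driven stop-codon changes at the
    C-terminus. Gene models are read from GTF plus transcript and protein
    FASTA inputs, with APPRIS-based reference isoform selection. A
    deterministic synthetic-gene generator covering the full event taxonomy
    and a brute-force codon-pairing oracle make the whole method testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: AlternativeSplicing, Transcriptomics, Annotation, Alignment
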