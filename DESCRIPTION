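Package: fmlseq
Title: Methylation Profiling by Fragmentation at Methylated Loci and Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational toolkit for methylation-dependent restriction
    digestion sequencing (FML-seq). Models the cut geometry of
    methylation-dependent endonucleases such as MspJI, scans reference
    genomes for recognition motifs on both strands, simulates digestion of
    methylated genome copies into paired-end sequencing libraries with
    ground-truth alignments, assigns read ends to motif sites by the
    expected fragment-end offset, aggregates hits over genomic regions,
    normalizes counts to reads per million per motif (RPMPM), and provides
    the cross-platform comparison statistics used to benchmark methylomes:
    coverage-weighted percent methylation, fragment-center counting,
    mean probe beta scores, chi-squared selection of variable regions,
    unit-interval scaling, UPGMA clustering on Pearson distances, and a
    ratio silhouette of class separation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    data.table,
    yaml,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
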