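Package: karyotypeR
Title: Karyotype and Aneuploidy Inference from Low-Coverage Sequencing Read Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers chromosomal karyotypes, including sex chromosome
    aneuploidies (47,XXY; 47,XYY; 45,X0; 47,XXX) and the viable autosomal
    trisomies (13, 18, 21), from per-chromosome aligned-read counts of
    shallow whole-genome or capture sequencing data, down to ~0.0001-fold
    coverage as is common in ancient DNA. Per-chromosome counts are
    compared against an autosomal baseline via ratio statistics (Rx, Ry,
    Rc) with binomial-approximation standard errors, and copy numbers are
    assigned against calibrated per-copy centroids. Includes contamination
    and mosaicism flagging, cohort-based recalibration, a multinomial
    count simulator for arbitrary karyotypes and two-individual
    contamination mixtures, binomial downsampling, and a power-analysis
    engine. Reads BAM/CRAM alignments, headerless SAM text streams, BED
    region masks, and TSV count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Coverage, CopyNumberVariation, Sequencing, Genetics
RoxygenNote: 7.3.3
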