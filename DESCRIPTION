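Package: genefam
Title: Gene-Family Characterization: Codon Usage, Duplication, Selection,
    Structure, Promoters, Expression and Phylogeny
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for genome-wide characterization of plant gene
    families, built around the basic helix-loop-helix (bHLH) transcription
    factor family in grapevine. Computes codon-usage-bias statistics (GC,
    GC3s, RSCU, Wright's effective number of codons with the expected
    ENC-GC3s curve, CAI, FOP, CBI) and their cross-gene correlations;
    detects duplicate gene pairs and triplicate groups from pairwise
    global protein alignments under two stringency standards and
    classifies duplication mechanism; estimates Ka, Ks and omega for
    paralog pairs by codon-aware back-translation and the Nei-Gojobori
    (1986) method with Jukes-Cantor correction; derives intron phases and
    symmetric-exon classes from GFF3 gene models; extracts promoters and
    scans them for IUPAC consensus cis-regulatory elements (G-box, E-box,
    ABRE, CRT/DRE and relatives); calls replicate-aware fold-change
    differential expression with a paired t-test on RMA-normalized
    intensities; and builds neighbor-joining protein trees with bootstrap
    support and clade calls. A synthetic-data generator produces every
    input type with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
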