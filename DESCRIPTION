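Package: cardioreg
Title: Integrative Analysis of Congenital Heart Disease SNPs in Regulatory and Coding Space
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for characterising congenital-heart-disease (CHD)
    associated variants. The noncoding branch expands CHD-SNPs into 150 bp
    windows, calls putative cardiac enhancers from histone-mark peak tracks
    across nine Carnegie stages of human heart organogenesis, classifies
    their developmental stage activity, scores evolutionary conservation
    against a resampled noncoding background, scans enhancer sequences for
    transcription-factor binding motifs with exact PWM p-values, and
    designates regulatory SNPs by cardiac eQTL intersection. The coding
    branch assembles a protein-protein interaction network, partitions it
    with a Markov Cluster implementation, and classifies missense mutations
    by their change in complex binding free energy. A seeded synthetic-data
    generator emulates every input at toy scale so the full pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
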