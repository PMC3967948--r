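Package: tbxsplice
Title: T-Box Factor Dependent Alternative Splicing Detection and Motif
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detection of transcription-factor dependent cassette-exon
    alternative splicing events from exon-level RNA-Seq counts using an
    RPKM-based filter cascade (Fisher's exact test, a q-value style
    Bayesian error rate, usage-ratio fold change, and read support),
    degenerate T-box binding element (TBE) motif scanning of alternative
    exons and their intronic flanks, affinity-purification mass
    spectrometry interactome filtering with category fold enrichment, and
    a three-exon splicing-reporter (minigene) model. Includes a seeded
    synthetic-data generator (annotation, genome, negative-binomial exon
    counts with planted inclusion changes, IP-MS detection matrices) so
    every stage is testable offline with known ground truth.
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
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
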