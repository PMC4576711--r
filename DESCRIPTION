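Package: ecosplice
Title: Comparative Alternative-Splicing Event Analysis Between Ecotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies alternative-splicing events (exon skipping,
    intron retention, alternative 5'-donor, alternative 3'-acceptor, and
    double-alternative splice sites) from spliced transcript alignments compared
    against per-gene exon-intron templates, confirms events with short-read
    splice junctions, partitions confirmed events and their genes into shared
    and ecotype-specific sets, computes a coverage-corrected alternative
    splicing index by repeated fixed-size subsampling of transcripts, and tests
    enrichment of event types and gene functions by randomization with
    empirical Z statistics and multiple-testing correction. Includes a
    seed-reproducible synthetic-data generator with a ground-truth manifest for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
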