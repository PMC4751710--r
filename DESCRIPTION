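Package: trackenrich
Title: Coverage-Based Enrichment Ranking of Genomic Signal Tracks
Version: 0.1.0
Authors@R:
    person("Track", "Enrich", email = "maintainer@trackenrich.dev", role = c("aut", "cre"))
Description: Ranks collections of bigWig coverage tracks (ChIP-seq, CAGE) by
    statistical over-representation of signal in a query set of genomic ranges
    relative to a background set. Gene, transcript and RefSeq identifiers are
    resolved to strand-aware promoter windows from a GTF annotation; the
    default background is a seeded sample of random gene promoters. Per-track
    length-normalized mean coverages are log-transformed and compared by a
    Welch two-sample t-test with Bonferroni correction, or by a parametric
    z-score for single-region inspection. Also produces center-anchored,
    5'-to-3' oriented average coverage profiles, per-interval coverage
    distributions, ranked report tables, and a fully synthetic fixture
    generator (toy genome, GTF, bigWig tracks with planted enrichment) for
    end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
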