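Package: venomsplice
Title: Isoform Classification and Alternative-Splicing Catalogs for Venom
    Gene Families from Long-Read Transcripts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies full-length long-read (Iso-Seq style) transcripts
    against annotated multigene venom gene models, calls alternative-splicing
    events (exon skipping, full and partial intron retention, alternative
    donor/acceptor sites, alternative first exons, alternative polyadenylation),
    re-projects open reading frames to determine protein consequences
    including snake-venom metalloproteinase P-I/P-II/P-III typing, detects
    trans-spliced chimeric transcripts across tandem gene clusters, and
    collapses reads into named transcript variants with per-gene and
    per-family summaries. Ships a deterministic synthetic-data generator that
    emulates venom-gland loci (metalloproteinase, serine protease, VEGF and
    phospholipase A2 architectures) with injected splice events, chimeras and
    truncated reads plus a ground-truth table, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
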