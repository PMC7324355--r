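Package: thripsis
Title: Reconstruction of Germline Chromothripsis from Long-Read Split Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rearranged long reads from split alignments (PAF/MAF),
    clusters reads sharing rearrangement junctions into groups, subtracts
    groups whose junctions recur in a control cohort, merges each surviving
    group into a breakpoint-level consensus rearrangement, and orders and
    orients the consensus rearrangements into derivative chromosomes with a
    uniqueness-checked end-matching algorithm. Deletions are inferred from the
    full reconstruction, gene impact is annotated from BED gene models, and
    relative expression is computed with the delta-delta-Ct method. A
    synthetic-data module generates toy genomes, planted chromothripsis
    rearrangement plans (including a canonical two-chromosome fixture with 19
    fragments, two derivatives and five deletions), simulated long reads and
    control cohorts with ground-truth tables, so the whole chain is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
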