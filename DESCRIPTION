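Package: nanotx
Title: ORF-Centric Classification of Long-Read Direct RNA-Seq Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies spliced long-read (nanopore direct RNA-seq) alignments
    against a compact genome, such as a DNA virus, into transcript groups
    defined by windowed transcription start/termination site clusters and
    exact splice-junction chains. Each group is annotated by the known
    protein it can encode using a 5'-extended pseudo-transcript and a
    5'-most-ORF / next-AUG rule, polyA tail dynamics are summarised and
    tested across time points with Wilcoxon signed-rank and Mann-Whitney U
    tests, and nanopore splice junctions are cross-validated against an
    independent short-read junction set. A bundled synthetic
    spliced-transcriptome simulator with full ground truth makes every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    methods,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
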